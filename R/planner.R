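# Osteotomy simulation core: hinge/entry construction, correction-angle
# solution by rigid rotation of the distal fragment about the hinge, and
# wedge-width measurement as the chord at the medial entry.

#' Planner configuration
#'
#' Collects the tunable planning parameters with their defaults.
#'
#' @param target_fraction Planned weight-bearing-line crossing as a fraction
#'   of the plateau width from the medial edge. Default 0.55, the classical
#'   slight lateral overcorrection target at the lateral intercondylar spine.
#' @param hinge_depth_mm Vertical depth of the hinge below the joint line,
#'   standing in for the level of the fibular head tip. Default 15 mm;
#'   results are first-order insensitive to it (it perturbs the osteotomy
#'   length by under 2%).
#' @param cortex_flare_deg Medial metaphyseal flare: the angle of the modelled
#'   medial cortex from the vertical, displacing the entry point medially by
#'   `height * tan(flare)`. Default 0 (vertical cortex).
#' @param saw_kerf_mm Additive allowance for saw-blade thickness on the
#'   reported wedge width. Default 0 (not part of the modelled geometry).
#' @param solver_tol Maximum residual on the achieved crossing fraction
#'   accepted from the correction-angle solver. Default 1e-10.
#' @param already_corrected What to do when a leg is already at or lateral to
#'   the target: `"warn"` (return a zero correction with a warning) or
#'   `"error"`.
#' @return A list of class `plan_config`.
#' @export
plan_config <- function(target_fraction = 0.55, hinge_depth_mm = 15,
                        cortex_flare_deg = 0, saw_kerf_mm = 0,
                        solver_tol = 1e-10,
                        already_corrected = c("warn", "error")) {
  stopifnot(is.finite(target_fraction), is.finite(hinge_depth_mm),
            hinge_depth_mm >= 0, is.finite(cortex_flare_deg),
            abs(cortex_flare_deg) < 90, is.finite(saw_kerf_mm),
            saw_kerf_mm >= 0, solver_tol > 0)
  structure(list(
    target_fraction   = target_fraction,
    hinge_depth_mm    = hinge_depth_mm,
    cortex_flare_deg  = cortex_flare_deg,
    saw_kerf_mm       = saw_kerf_mm,
    solver_tol        = solver_tol,
    already_corrected = match.arg(already_corrected)
  ), class = "plan_config")
}

#' Lateral hinge point
#'
#' Places the hinge at a horizontal offset medial to the lateral plateau edge
#' and at a vertical depth below the joint line.
#'
#' @param leg A [`leg_geometry`][make_leg] object.
#' @param dist_from_lateral Horizontal offset from the lateral cortical wall,
#'   mm; must lie strictly inside the plateau.
#' @param hinge_depth Depth below the joint line, mm (>= 0). Default 15.
#' @return The hinge point `c(x, y)` in mm.
#' @export
hinge_point <- function(leg, dist_from_lateral, hinge_depth = 15) {
  stopifnot(inherits(leg, "leg_geometry"))
  if (!is.finite(dist_from_lateral) || dist_from_lateral <= 0 ||
      dist_from_lateral >= leg$plateau_width) {
    stop("hinge offset must lie strictly inside the plateau width",
         call. = FALSE)
  }
  if (!is.finite(hinge_depth) || hinge_depth < 0) {
    stop("hinge depth must be non-negative", call. = FALSE)
  }
  leg$plateau_lateral + dist_from_lateral * .medial_unit(leg) +
    hinge_depth * .distal_unit(leg)
}

#' Medial osteotomy entry point
#'
#' Point on the modelled medial cortex at a given distance below the medial
#' plateau edge. With a non-zero flare angle the cortex line tilts medially,
#' displacing the entry by `height * tan(flare)`.
#'
#' @param leg A [`leg_geometry`][make_leg] object.
#' @param height_below_plateau Distance below the medial plateau edge, mm
#'   (> 0).
#' @param cortex_flare_deg Medial cortex flare from vertical, degrees.
#' @return The entry point `c(x, y)` in mm.
#' @export
medial_entry <- function(leg, height_below_plateau, cortex_flare_deg = 0) {
  stopifnot(inherits(leg, "leg_geometry"))
  if (!is.finite(height_below_plateau) || height_below_plateau <= 0) {
    stop("osteotomy height below the plateau must be positive", call. = FALSE)
  }
  leg$plateau_medial + height_below_plateau * .distal_unit(leg) +
    height_below_plateau * tan(cortex_flare_deg * pi / 180) * .medial_unit(leg)
}

#' Opening-wedge width for a given cut length and correction angle
#'
#' The chord opening at the medial entry of an osteotomy of length `L` hinged
#' at its lateral end and opened by `alpha`: `2 * L * sin(alpha / 2)`.
#'
#' @param L Osteotomy length (entry to hinge), mm; must be non-negative.
#' @param alpha Opening angle in degrees, in `[0, 180)`.
#' @return Wedge width in mm.
#' @examples
#' wedge_width(75, 7) # 2 * 75 * sin(3.5 deg) = 9.157 mm
#' @export
wedge_width <- function(L, alpha) {
  if (any(!is.finite(L)) || any(L < 0)) {
    stop("osteotomy length must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha >= 180)) {
    stop("opening angle must be in [0, 180) degrees", call. = FALSE)
  }
  2 * L * sin(alpha * pi / 360)
}

# rotation sense (+1 CCW / -1 CW) that moves the WBL crossing laterally,
# determined numerically from the landmarks so mirrored legs work unchanged
.valgus_sense <- function(leg, hinge) {
  f0 <- wbl_fraction(leg)
  fp <- .wbl_fraction_pts(leg$hip_center,
                          .rotate(leg$ankle_center, hinge, 1e-7),
                          leg$plateau_medial, leg$plateau_lateral)
  if (fp > f0) 1 else -1
}

#' Solve the valgising correction angle about a hinge
#'
#' Finds the unique rotation of the distal fragment (the ankle centre and
#' everything distal to the osteotomy) about the hinge, in the
#' valgus-producing direction, after which the hip--ankle line crosses the
#' joint line at `target_fraction`. The root is bracketed on
#' `[0, max_angle]` degrees and solved by [stats::uniroot()]; the residual of
#' the achieved fraction is checked against `tol`.
#'
#' @param leg A [`leg_geometry`][make_leg] object with a crossing medial to
#'   the target (varus needing valgisation).
#' @param hinge Hinge point `c(x, y)` in mm, e.g. from [hinge_point()].
#' @param target_fraction Target crossing fraction, default 0.55.
#' @param tol Maximum accepted residual on the crossing fraction.
#' @param max_angle Upper bracket in degrees, default 45.
#' @param already_corrected Behaviour when the leg is already at or lateral
#'   to the target: `"warn"` returns 0 with a warning, `"error"` stops.
#' @return The correction angle in degrees (>= 0).
#' @export
solve_correction_angle <- function(leg, hinge, target_fraction = 0.55,
                                   tol = 1e-10, max_angle = 45,
                                   already_corrected = c("warn", "error")) {
  stopifnot(inherits(leg, "leg_geometry"), length(hinge) == 2,
            all(is.finite(hinge)))
  already_corrected <- match.arg(already_corrected)
  f0 <- wbl_fraction(leg) - target_fraction
  if (f0 >= 0) {
    msg <- "weight-bearing line already at or lateral to the target; no valgisation needed"
    if (already_corrected == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    return(0)
  }
  s <- .valgus_sense(leg, hinge)
  g <- function(a) {
    .wbl_fraction_pts(leg$hip_center,
                      .rotate(leg$ankle_center, hinge, s * a * pi / 180),
                      leg$plateau_medial, leg$plateau_lateral) -
      target_fraction
  }
  if (g(max_angle) < 0) {
    stop(sprintf("no correction angle within [0, %g] degrees reaches the target",
                 max_angle), call. = FALSE)
  }
  root <- stats::uniroot(g, c(0, max_angle), tol = 1e-13,
                         maxiter = 2000L)$root
  if (abs(g(root)) > tol) {
    stop("correction-angle solver did not converge to the requested tolerance",
         call. = FALSE)
  }
  root
}

#' Apply a hinge rotation to the distal fragment
#'
#' Rotates the ankle centre about the hinge by `alpha` degrees in the
#' valgus-producing direction and returns the corrected leg (knee, hip and
#' plateau belong to the proximal fragment and do not move). The tibial
#' length and varus angle fields are recomputed; opening a wedge lengthens
#' the limb slightly.
#'
#' @param leg A [`leg_geometry`][make_leg] object.
#' @param hinge Hinge point `c(x, y)` in mm.
#' @param alpha Opening angle in degrees (>= 0).
#' @return The corrected `leg_geometry`.
#' @export
apply_correction <- function(leg, hinge, alpha) {
  stopifnot(inherits(leg, "leg_geometry"), alpha >= 0)
  s <- .valgus_sense(leg, hinge)
  leg$ankle_center <- .rotate(leg$ankle_center, hinge, s * alpha * pi / 180)
  leg$tibial_length <- sqrt(sum((leg$ankle_center - leg$knee_center)^2))
  leg$varus_angle <- mfta(leg)
  leg
}

#' Crossing fraction achieved by a fixed wedge width
#'
#' Inverse planning check: given an executed wedge of width `wedge_mm` opened
#' about the condition's hinge, recover the opening angle from the chord
#' identity and report where the weight-bearing line ends up. Used to study
#' under-/over-correction when the intraoperative hinge differs from the
#' planned one.
#'
#' @param leg A [`leg_geometry`][make_leg] object (pre-operative).
#' @param wedge_mm Executed wedge width, mm.
#' @param height_below_plateau Medial entry height, mm.
#' @param dist_from_lateral Hinge offset from the lateral wall, mm.
#' @param config A [plan_config()].
#' @return The achieved crossing fraction.
#' @export
achieved_fraction <- function(leg, wedge_mm, height_below_plateau,
                              dist_from_lateral, config = plan_config()) {
  stopifnot(wedge_mm >= 0)
  entry <- medial_entry(leg, height_below_plateau, config$cortex_flare_deg)
  hinge <- hinge_point(leg, dist_from_lateral, config$hinge_depth_mm)
  L <- sqrt(sum((entry - hinge)^2))
  if (wedge_mm > 2 * L) {
    stop("wedge width exceeds twice the osteotomy length", call. = FALSE)
  }
  alpha <- 2 * asin(wedge_mm / (2 * L)) * 180 / pi
  wbl_fraction(apply_correction(leg, hinge, alpha))
}

.condition_label <- function(height_mm, dist_mm) {
  letters3 <- c("5" = "A", "10" = "B", "15" = "C")
  if (height_mm %in% c(30, 40) && dist_mm %in% c(5, 10, 15)) {
    sprintf("%dcm-%s", height_mm / 10, letters3[[as.character(dist_mm)]])
  } else {
    sprintf("h%gmm-d%gmm", height_mm, dist_mm)
  }
}

#' Plan one medial opening-wedge osteotomy
#'
#' Composes [medial_entry()], [hinge_point()], [solve_correction_angle()] and
#' [wedge_width()] into a full planning solution for one knee and one
#' condition.
#'
#' @param leg A [`leg_geometry`][make_leg] object.
#' @param height_below_plateau Medial entry height below the plateau, mm.
#' @param dist_from_lateral Hinge offset from the lateral wall, mm.
#' @param config A [plan_config()].
#' @return An object of class `osteotomy_plan`: entry and hinge points,
#'   osteotomy length `L` (mm), correction angle (degrees), wedge width (mm,
#'   the chord `2 L sin(alpha/2)` plus any saw-kerf allowance), the target
#'   and achieved crossing fractions, and a condition label (`"3cm-A"` style
#'   for the six canonical conditions).
#' @examples
#' leg <- make_leg(6)
#' plan_osteotomy(leg, height_below_plateau = 40, dist_from_lateral = 15)
#' @export
plan_osteotomy <- function(leg, height_below_plateau, dist_from_lateral,
                           config = plan_config()) {
  stopifnot(inherits(leg, "leg_geometry"), inherits(config, "plan_config"))
  entry <- medial_entry(leg, height_below_plateau, config$cortex_flare_deg)
  hinge <- hinge_point(leg, dist_from_lateral, config$hinge_depth_mm)
  alpha <- solve_correction_angle(
    leg, hinge,
    target_fraction   = config$target_fraction,
    tol               = config$solver_tol,
    already_corrected = config$already_corrected
  )
  L <- sqrt(sum((entry - hinge)^2))
  structure(list(
    entry_point       = entry,
    hinge_point       = hinge,
    osteotomy_length  = L,
    correction_angle  = alpha,
    wedge_width       = wedge_width(L, alpha) + config$saw_kerf_mm,
    target_fraction   = config$target_fraction,
    achieved_fraction = wbl_fraction(apply_correction(leg, hinge, alpha)),
    condition_label   = .condition_label(height_below_plateau,
                                         dist_from_lateral),
    height_mm         = height_below_plateau,
    hinge_offset_mm   = dist_from_lateral
  ), class = "osteotomy_plan")
}

#' @export
print.osteotomy_plan <- function(x, ...) {
  cat(sprintf("<osteotomy_plan> %s: L = %.1f mm, correction %.2f deg, wedge %.2f mm\n",
              x$condition_label, x$osteotomy_length, x$correction_angle,
              x$wedge_width))
  cat(sprintf("  WBL target %.0f%%, achieved %.2f%%\n",
              100 * x$target_fraction, 100 * x$achieved_fraction))
  invisible(x)
}
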