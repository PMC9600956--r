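# Coronal-plane (2D) landmark model of a lower limb and its alignment
# measures. All coordinates are in millimetres; angles cross the interface in
# degrees and are converted to radians internally.

#' Construct a coronal-plane leg geometry
#'
#' Embeds the printed descriptors of a lower limb (varus angle, bone lengths,
#' plateau width) into a canonical 2D coordinate frame: knee centre at the
#' origin, femoral mechanical axis vertical (hip at `(0, femoral_length)`),
#' joint line horizontal, and the ankle placed at `tibial_length` from the
#' knee, rotated medially from the vertical by `varus_angle` so that for
#' varus > 0 the hip--ankle (Mikulicz) line crosses the joint line medial to
#' the knee centre. For a right leg the +x axis points laterally; a left leg
#' is the mirror image (x negated), with the medial/lateral plateau landmarks
#' keeping their anatomical meaning.
#'
#' The whole deformity is placed in the proximal tibia (apex at the knee) and
#' the femur is modelled as neutral: mOWHTO corrects a tibial deformity and
#' only the overall mechanical femorotibial angle is modelled, not the
#' femoral and tibial partial angles. Joint-line obliquity is not modelled.
#'
#' @param varus_angle Signed coronal deformity in degrees, varus positive.
#'   Must satisfy `|varus_angle| < 45`.
#' @param femoral_length Hip-to-knee distance in mm (> 0).
#' @param tibial_length Knee-to-ankle distance in mm (> 0).
#' @param plateau_width Medial-to-lateral tibial plateau width in mm (> 0);
#'   the knee centre is its midpoint.
#' @param side `"right"` or `"left"`; mirroring changes coordinates only,
#'   never any alignment measure or wedge width.
#' @return An object of class `leg_geometry`: a list with point fields
#'   `hip_center`, `knee_center`, `ankle_center`, `plateau_medial`,
#'   `plateau_lateral` (each `c(x, y)` in mm) and scalar fields
#'   `plateau_width`, `femoral_length`, `tibial_length`, `varus_angle`,
#'   `side`.
#' @seealso [mfta()], [wbl_fraction()], [mirror_leg()]
#' @examples
#' leg <- make_leg(6, 475, 372.6, 79.5)
#' mfta(leg)          # 6 (constructor round-trip)
#' wbl_fraction(leg)  # < 0.5: crossing medial of the plateau centre
#' @export
make_leg <- function(varus_angle, femoral_length = 475, tibial_length = 372.6,
                     plateau_width = 79.5, side = c("right", "left")) {
  side <- match.arg(side)
  vals <- c(varus_angle, femoral_length, tibial_length, plateau_width)
  if (!all(is.finite(vals))) {
    stop("all leg parameters must be finite numbers", call. = FALSE)
  }
  if (femoral_length <= 0 || tibial_length <= 0 || plateau_width <= 0) {
    stop("bone lengths and plateau width must be positive", call. = FALSE)
  }
  if (abs(varus_angle) >= 45) {
    stop("|varus_angle| must be below 45 degrees", call. = FALSE)
  }
  v <- varus_angle * pi / 180
  leg <- structure(list(
    side            = "right",
    hip_center      = c(0, femoral_length),
    knee_center     = c(0, 0),
    ankle_center    = c(-tibial_length * sin(v), -tibial_length * cos(v)),
    plateau_medial  = c(-plateau_width / 2, 0),
    plateau_lateral = c(plateau_width / 2, 0),
    plateau_width   = plateau_width,
    femoral_length  = femoral_length,
    tibial_length   = tibial_length,
    varus_angle     = varus_angle
  ), class = "leg_geometry")
  if (side == "left") leg <- mirror_leg(leg)
  leg
}

#' Mirror a leg about the body midline
#'
#' Negates all x coordinates and swaps the side label. The medial and lateral
#' plateau landmarks keep their anatomical meaning, so every alignment
#' measure and every wedge width is invariant under mirroring.
#'
#' @param leg A [`leg_geometry`][make_leg] object.
#' @return The mirrored `leg_geometry`.
#' @export
mirror_leg <- function(leg) {
  stopifnot(inherits(leg, "leg_geometry"))
  for (f in c("hip_center", "knee_center", "ankle_center",
              "plateau_medial", "plateau_lateral")) {
    leg[[f]][1] <- -leg[[f]][1]
  }
  leg$side <- if (identical(leg$side, "right")) "left" else "right"
  leg
}

# unit vector from the lateral to the medial plateau edge
.medial_unit <- function(leg) {
  (leg$plateau_medial - leg$plateau_lateral) / leg$plateau_width
}

# unit vector perpendicular to the joint line, pointing distally (ankle side)
.distal_unit <- function(leg) {
  u <- leg$plateau_lateral - leg$plateau_medial
  n <- c(-u[2], u[1]) / sqrt(sum(u^2))
  if (sum(n * (leg$ankle_center - leg$knee_center)) < 0) n <- -n
  n
}

#' Mechanical femorotibial angle (mFTA)
#'
#' Angle between the femoral (hip to knee) and tibial (knee to ankle)
#' mechanical axes, signed varus-positive: positive when the ankle lies
#' medial to the distal extension of the femoral axis.
#'
#' @param leg A [`leg_geometry`][make_leg] object.
#' @return The mFTA in degrees (varus positive).
#' @export
mfta <- function(leg) {
  stopifnot(inherits(leg, "leg_geometry"))
  a <- leg$knee_center - leg$hip_center
  b <- leg$ankle_center - leg$knee_center
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("degenerate mechanical axis of zero length", call. = FALSE)
  }
  ang <- atan2(abs(a[1] * b[2] - a[2] * b[1]), sum(a * b)) * 180 / pi
  if (ang == 0) return(0)
  # side of the deviation: project the ankle's offset from the collinear
  # position onto the medial direction
  p <- leg$knee_center + a / na * nb
  s <- sum((leg$ankle_center - p) * .medial_unit(leg))
  ang * sign(s)
}

#' Weight-bearing-line crossing fraction of the tibial plateau
#'
#' Intersects the hip--ankle (Mikulicz) line with the infinite joint line and
#' expresses the crossing as a fraction of the plateau width measured from
#' the medial edge: 0 is the medial edge, 1 the lateral edge, 0.5 the knee
#' centre. Values outside \[0, 1\] indicate the crossing falls beyond the
#' bony plateau (severe deformity).
#'
#' @param leg A [`leg_geometry`][make_leg] object.
#' @return The crossing fraction (unitless).
#' @export
wbl_fraction <- function(leg) {
  stopifnot(inherits(leg, "leg_geometry"))
  .wbl_fraction_pts(leg$hip_center, leg$ankle_center,
                    leg$plateau_medial, leg$plateau_lateral)
}

# fraction from raw points; shared with the correction-angle solver so the
# solved rotation is evaluated with the same intersection code
.wbl_fraction_pts <- function(hip, ankle, pm, pl) {
  u <- pl - pm
  w <- ankle - hip
  det <- u[1] * (-w[2]) + w[1] * u[2]
  if (abs(det) < 1e-12 * sqrt(sum(u^2)) * sqrt(sum(w^2))) {
    stop("weight-bearing line is parallel to the joint line", call. = FALSE)
  }
  b <- hip - pm
  (b[1] * (-w[2]) + w[1] * b[2]) / det
}

# rotate point p about `center` by `theta` radians (counter-clockwise)
.rotate <- function(p, center, theta) {
  d <- p - center
  c(center[1] + d[1] * cos(theta) - d[2] * sin(theta),
    center[2] + d[1] * sin(theta) + d[2] * cos(theta))
}

#' @export
print.leg_geometry <- function(x, ...) {
  cat(sprintf("<leg_geometry> %s leg: varus %.2f deg, plateau %.1f mm, femur %.1f mm, tibia %.1f mm\n",
              x$side, x$varus_angle, x$plateau_width, x$femoral_length,
              x$tibial_length))
  cat(sprintf("  WBL crossing at %.1f%% of the plateau from medial\n",
              100 * wbl_fraction(x)))
  invisible(x)
}
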