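# Six-condition experiment over a cohort: per-knee planning under every
# osteotomy-height x hinge-offset combination, condition summaries, paired
# per-knee differences and bone-length correlations.

#' Plan every knee of a cohort under every condition
#'
#' Runs [plan_osteotomy()] for each knee and each combination of osteotomy
#' height and hinge offset (defaults: heights 30 and 40 mm by offsets 5, 10
#' and 15 mm, i.e. the six canonical conditions 3cm-A ... 4cm-C). Solver
#' failures are recorded per row and do not abort the run.
#'
#' @param cohort A cohort `data.frame` from [generate_cohort()].
#' @param heights Osteotomy heights below the medial plateau, mm.
#' @param hinge_offsets Hinge offsets from the lateral wall, mm.
#' @param config A [plan_config()].
#' @return A `data.frame` (one row per knee x condition) with columns
#'   `knee_id`, `condition`, `height_mm`, `hinge_mm`, `wedge_mm`,
#'   `alpha_deg`, `L_mm`, `achieved_fraction`, `error` (NA when the plan
#'   succeeded).
#' @export
run_conditions <- function(cohort, heights = c(30, 40),
                           hinge_offsets = c(5, 10, 15),
                           config = plan_config()) {
  stopifnot(nrow(cohort) >= 1, length(heights) >= 1,
            length(hinge_offsets) >= 1)
  legs <- cohort_legs(cohort)
  grid <- expand.grid(knee = seq_len(nrow(cohort)), height = heights,
                      hinge = hinge_offsets, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    k <- grid$knee[i]
    h <- grid$height[i]
    d <- grid$hinge[i]
    res <- tryCatch(plan_osteotomy(legs[[k]], h, d, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(knee_id = cohort$knee_id[k],
                 condition = .condition_label(h, d),
                 height_mm = h, hinge_mm = d,
                 wedge_mm = NA_real_, alpha_deg = NA_real_, L_mm = NA_real_,
                 achieved_fraction = NA_real_,
                 error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(knee_id = cohort$knee_id[k],
                 condition = res$condition_label,
                 height_mm = h, hinge_mm = d,
                 wedge_mm = res$wedge_width,
                 alpha_deg = res$correction_angle,
                 L_mm = res$osteotomy_length,
                 achieved_fraction = res$achieved_fraction,
                 error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$knee_id), ]
  rownames(out) <- NULL
  out
}

#' Per-condition wedge-width summary
#'
#' @param wedges A wedge table from [run_conditions()].
#' @return A `data.frame` with one row per condition: `condition`, `n`,
#'   `mean_wedge_mm`, `sd_wedge_mm`, `mean_alpha_deg`.
#' @export
condition_summary <- function(wedges) {
  if (is.null(wedges) || nrow(wedges) == 0) {
    stop("empty wedge table", call. = FALSE)
  }
  ok <- wedges[is.na(wedges$error), ]
  if (nrow(ok) == 0) stop("no successful plans in the wedge table", call. = FALSE)
  split_w <- split(ok, ok$condition)
  out <- do.call(rbind, lapply(names(split_w), function(cond) {
    s <- split_w[[cond]]
    data.frame(condition = cond, n = nrow(s),
               mean_wedge_mm = mean(s$wedge_mm),
               sd_wedge_mm = stats::sd(s$wedge_mm),
               mean_alpha_deg = mean(s$alpha_deg),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Paired per-knee wedge-width differences between conditions
#'
#' For every unordered pair of conditions, the difference of the condition
#' means and the percentage of knees whose individual wedge widths differ by
#' at least `threshold` (the clinical-relevance cut-off).
#'
#' @param wedges A wedge table from [run_conditions()]; every condition must
#'   contain the same knees (paired design).
#' @param threshold Per-knee relevance threshold in mm, default 2.
#' @return A `data.frame` with one row per pair: `pair`, `cond1`, `cond2`,
#'   `mean_diff_mm` (mean of `cond1` minus mean of `cond2`),
#'   `rate_ge_threshold_pct`.
#' @export
pairwise_differences <- function(wedges, threshold = 2) {
  stopifnot(threshold >= 0)
  ok <- wedges[is.na(wedges$error), ]
  conds <- sort(unique(ok$condition))
  if (length(conds) < 2) stop("need at least two conditions", call. = FALSE)
  by_cond <- split(ok, ok$condition)
  ids <- lapply(by_cond, function(s) sort(s$knee_id))
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]]))) {
    stop("conditions are not paired on the same knees", call. = FALSE)
  }
  vals <- lapply(by_cond, function(s) s$wedge_mm[order(s$knee_id)])
  pairs <- utils::combn(conds, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    c1 <- pairs[1, j]
    c2 <- pairs[2, j]
    d <- vals[[c1]] - vals[[c2]]
    data.frame(pair = paste(c1, "vs", c2), cond1 = c1, cond2 = c2,
               mean_diff_mm = mean(d),
               rate_ge_threshold_pct = 100 * mean(abs(d) >= threshold),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pearson correlations of wedge width with bone lengths
#'
#' @param wedges A wedge table from [run_conditions()].
#' @param cohort The cohort the table was computed from.
#' @return A `data.frame` with one row per condition x bone length:
#'   `condition`, `bone`, `r`, `p_value`.
#' @export
length_correlations <- function(wedges, cohort) {
  ok <- wedges[is.na(wedges$error), ]
  merged <- merge(ok, as.data.frame(cohort), by = "knee_id")
  bones <- c(femoral = "femoral_length_mm", tibial = "tibial_length_mm")
  out <- do.call(rbind, lapply(sort(unique(merged$condition)), function(cond) {
    s <- merged[merged$condition == cond, ]
    do.call(rbind, lapply(names(bones), function(b) {
      x <- s$wedge_mm
      y <- s[[bones[[b]]]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        stop("zero-variance input: correlation undefined", call. = FALSE)
      }
      ct <- stats::cor.test(x, y, method = "pearson")
      data.frame(condition = cond, bone = b, r = unname(ct$estimate),
                 p_value = ct$p.value, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
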