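# Statistical battery: one-way ANOVA, Tukey HSD (studentized range),
# ICC(A,k) absolute-agreement intraclass correlation with its F-based
# confidence interval, and the Landis-style agreement grading.

.as_group_frame <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    return(data.frame(value = groups$value, group = factor(groups$group)))
  }
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) across
#' groups of wedge widths. The six planning conditions are treated as
#' independent groups here even though knees are paired across conditions;
#' the paired information enters through [pairwise_differences()] instead.
#'
#' @param groups A list of numeric vectors (>= 2 groups, each n >= 2), or a
#'   `data.frame` with columns `value` and `group`.
#' @return A list with `statistic` (F), `p_value`, `df_between`, `df_within`.
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6)))$statistic # 13.5
#' @export
anova_oneway <- function(groups) {
  d <- .as_group_frame(groups)
  if (nlevels(d$group) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(d$group) < 2)) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  k <- nlevels(d$group)
  df1 <- k - 1L
  df2 <- nrow(d) - k
  if (stats::var(d$value) == 0) {
    # all values identical: no between- or within-group variability
    return(list(statistic = 0, p_value = 1, df_between = df1, df_within = df2))
  }
  ft <- stats::oneway.test(value ~ group, data = d, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p_value = unname(ft$p.value),
       df_between = df1, df_within = df2)
}

#' Tukey HSD all-pairs comparisons
#'
#' Simultaneous mean differences, 95% confidence intervals and adjusted
#' p-values from the studentized-range distribution with `N - k` error
#' degrees of freedom (Tukey-Kramer for unbalanced groups), as implemented
#' by [stats::TukeyHSD()] on a one-way fit.
#'
#' @inheritParams anova_oneway
#' @param conf_level Simultaneous confidence level, default 0.95.
#' @return A `data.frame` with one row per unordered pair: `pair`, `diff`
#'   (second-level mean minus first-level mean, following the level order of
#'   the input), `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(groups, conf_level = 0.95) {
  d <- .as_group_frame(groups)
  if (nlevels(d$group) < 2) stop("need at least two groups", call. = FALSE)
  if (stats::var(d$value) == 0) {
    # degenerate: identical data in every group -> all contrasts are null
    cmb <- utils::combn(levels(d$group), 2)
    return(data.frame(pair = paste(cmb[2, ], cmb[1, ], sep = "-"),
                      diff = 0, lwr = 0, upr = 0, p_adj = 1,
                      stringsAsFactors = FALSE))
  }
  fit <- stats::aov(value ~ group, data = d)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intraclass correlation ICC(A,k): two-way model, absolute agreement,
#' average of k ratings
#'
#' From the two-way mean squares of a complete subjects-by-raters table
#' (rows `MS_R`, columns `MS_C`, error `MS_E`):
#' \deqn{ICC(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}}
#' with the F-based 95% confidence interval of the McGraw-Wong convention
#' (interval for the single-rating ICC(A,1) with Satterthwaite degrees of
#' freedom, stepped up by the Spearman-Brown relation). The estimate is
#' clamped to `[-1, 1]`.
#'
#' The same operation serves both reliability layouts: sessions-as-columns
#' for intra-rater reproducibility and raters-as-columns for inter-rater
#' reliability.
#'
#' @param values A complete numeric matrix, subjects in rows, ratings
#'   (raters or sessions) in columns; >= 2 subjects and >= 2 columns, no
#'   missing cells.
#' @param conf_level Confidence level, default 0.95.
#' @return A list of class `icc_ak`: `estimate`, `ci_lower`, `ci_upper`,
#'   `grade` (Landis label of the estimate), `n`, `k`, and the mean squares
#'   `ms = c(MSR, MSC, MSE)`.
#' @export
icc_ak <- function(values, conf_level = 0.95) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("the reliability table must be complete", call. = FALSE)
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2 || k < 2) {
    stop("need at least 2 subjects and 2 ratings", call. = FALSE)
  }
  g <- mean(values)
  rmean <- rowMeans(values)
  cmean <- colMeans(values)
  ssr <- k * sum((rmean - g)^2)
  ssc <- n * sum((cmean - g)^2)
  sse <- sum((values - outer(rmean, rep(1, k)) -
                outer(rep(1, n), cmean) + g)^2)
  if (ssr <= 1e-12 * max(1, sum(values^2))) {
    stop("zero between-subject variance: ICC undefined", call. = FALSE)
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (msc - mse) / n)
  est <- max(-1, min(1, est))
  if (mse == 0 && msc == 0) {
    ci <- c(est, est) # perfect agreement: interval degenerates
  } else {
    mse_s <- max(mse, .Machine$double.xmin)
    icc1 <- (msr - mse_s) / (msr + (k - 1) * mse_s + k * (msc - mse_s) / n)
    fj <- msc / mse_s
    alpha <- 1 - conf_level
    vn <- (k - 1) * (n - 1) *
      (k * icc1 * fj + n * (1 + (k - 1) * icc1) - k * icc1)^2
    vd <- (n - 1) * k^2 * icc1^2 * fj^2 +
      (n * (1 + (k - 1) * icc1) - k * icc1)^2
    v <- vn / vd
    fu <- stats::qf(1 - alpha / 2, n - 1, v)
    fl <- stats::qf(1 - alpha / 2, v, n - 1)
    l1 <- n * (msr - fu * mse_s) /
      (fu * (k * msc + (k * n - k - n) * mse_s) + n * msr)
    u1 <- n * (fl * msr - mse_s) /
      (k * msc + (k * n - k - n) * mse_s + n * fl * msr)
    ci <- c(l1 * k / (1 + (k - 1) * l1), u1 * k / (1 + (k - 1) * u1))
    ci <- pmax(-1, pmin(1, ci))
  }
  structure(list(estimate = est, ci_lower = ci[1], ci_upper = ci[2],
                 grade = landis_grade(est), n = n, k = k,
                 ms = c(MSR = msr, MSC = msc, MSE = mse)),
            class = "icc_ak")
}

#' @export
print.icc_ak <- function(x, ...) {
  cat(sprintf("ICC(A,%d) = %.3f (%.3f-%.3f), %s agreement [n = %d]\n",
              x$k, x$estimate, x$ci_lower, x$ci_upper, x$grade, x$n))
  invisible(x)
}

#' Landis-style agreement grade of an ICC
#'
#' Bins: below 0 `poor`; 0-0.20 `slight`; 0.21-0.40 `fair`; 0.41-0.60
#' `moderate`; 0.61-0.80 `substantial`; above 0.80 `(almost) perfect`. The
#' gaps between printed bin edges (e.g. 0.20 vs 0.21) are resolved by
#' half-up rounding to two decimals, i.e. bin boundaries at 0.205, 0.405,
#' 0.605 and 0.805 with the boundary itself belonging to the upper bin.
#'
#' @param icc Numeric ICC value(s) in `[-1, 1]`.
#' @return Character grade label(s).
#' @export
landis_grade <- function(icc) {
  if (any(!is.finite(icc)) || any(icc < -1) || any(icc > 1)) {
    stop("ICC must lie in [-1, 1]", call. = FALSE)
  }
  ifelse(icc < 0, "poor",
    ifelse(icc < 0.205, "slight",
      ifelse(icc < 0.405, "fair",
        ifelse(icc < 0.605, "moderate",
          ifelse(icc < 0.805, "substantial", "(almost) perfect")))))
}

#' Reliability layouts from a subjects x raters x sessions array
#'
#' Splits a [simulate_raters()] array into the two complete two-way tables
#' the reliability analysis needs: one intra-rater table per rater (subjects
#' x sessions) and one inter-rater table (subjects x raters, first session).
#'
#' @param tab A 3D array `subjects x raters x sessions`.
#' @return A named list of matrices: `intra_rater1`, `intra_rater2`, ...,
#'   and `inter_rater`.
#' @export
reliability_layouts <- function(tab) {
  stopifnot(is.array(tab), length(dim(tab)) == 3)
  n_raters <- dim(tab)[2]
  out <- lapply(seq_len(n_raters), function(r) tab[, r, , drop = TRUE])
  names(out) <- paste0("intra_rater", seq_len(n_raters))
  out$inter_rater <- tab[, , 1, drop = TRUE]
  out
}
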