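# Independent oracles used to cross-check the implementation. These
# deliberately take different computational routes from the package code.

# line-line intersection via homogeneous coordinates (cross products),
# returned as the fraction of |pm -> pl| from pm
oracle_fraction <- function(hip, ankle, pm, pl) {
  cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
  l1 <- cross3(c(hip, 1), c(ankle, 1))
  l2 <- cross3(c(pm, 1), c(pl, 1))
  p <- cross3(l1, l2)
  stopifnot(abs(p[3]) > 1e-12)
  p <- p[1:2] / p[3]
  sum((p - pm) * (pl - pm)) / sum((pl - pm)^2)
}

# unsigned angle between two vectors, degrees, via the clamped arccosine
oracle_angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# brute-force grid search for the correction angle: sweep alpha and minimise
# |achieved fraction - target|; own rotation and intersection code
oracle_grid_alpha <- function(leg, hinge, target = 0.55, step = 0.001,
                              max_deg = 25) {
  alphas <- seq(0, max_deg, by = step)
  th <- alphas * pi / 180
  d <- leg$ankle_center - hinge
  ax <- hinge[1] + d[1] * cos(th) - d[2] * sin(th)
  ay <- hinge[2] + d[1] * sin(th) + d[2] * cos(th)
  hip <- leg$hip_center
  pm <- leg$plateau_medial
  pl <- leg$plateau_lateral
  # intersection parameter of hip->ankle with pm->pl, vectorised Cramer
  ux <- pl[1] - pm[1]; uy <- pl[2] - pm[2]
  wx <- ax - hip[1];   wy <- ay - hip[2]
  det <- ux * (-wy) + wx * uy
  bx <- hip[1] - pm[1]; by <- hip[2] - pm[2]
  fr <- (bx * (-wy) + wx * by) / det
  best <- which.min(abs(fr - target))
  # the sweep above rotates counter-clockwise; mirror-image legs valgise
  # clockwise, so sweep the other way too and keep the better of the two
  ax2 <- hinge[1] + d[1] * cos(th) + d[2] * sin(th)
  ay2 <- hinge[2] - d[1] * sin(th) + d[2] * cos(th)
  wx2 <- ax2 - hip[1]; wy2 <- ay2 - hip[2]
  det2 <- ux * (-wy2) + wx2 * uy
  fr2 <- (bx * (-wy2) + wx2 * by) / det2
  best2 <- which.min(abs(fr2 - target))
  if (abs(fr2[best2] - target) < abs(fr[best] - target)) alphas[best2]
  else alphas[best]
}

# one-way ANOVA from explicit sums of squares
oracle_anova_F <- function(groups) {
  all <- unlist(groups)
  g <- mean(all)
  ssb <- sum(vapply(groups, function(x) length(x) * (mean(x) - g)^2, 0))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Monte-Carlo adjusted p for one Tukey contrast in a balanced design:
# the null distribution of the studentized range statistic is simulated and
# the observed pairwise q is referred to it
oracle_tukey_p_mc <- function(groups, pair = c(1, 2), nsim = 1e5,
                              seed = 424242) {
  k <- length(groups)
  n <- length(groups[[1]])
  stopifnot(all(lengths(groups) == n))
  msw <- mean(vapply(groups, stats::var, 0))
  se <- sqrt(msw / n)
  q_obs <- abs(mean(groups[[pair[1]]]) - mean(groups[[pair[2]]])) / se
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- array(stats::rnorm(nsim * k * n), dim = c(nsim, k, n))
  gm <- apply(x, c(1, 2), mean)
  gv <- apply(x, c(1, 2), stats::var)
  q_sim <- (apply(gm, 1, max) - apply(gm, 1, min)) /
    sqrt(rowMeans(gv) / n)
  mean(q_sim >= q_obs)
}

# ICC(A,k) via an explicit variance-components decomposition, with the mean
# squares taken from a two-way aov fit rather than hand-rolled sums
oracle_icc_varcomp <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values)
  k <- ncol(values)
  d <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  sig_r <- (msr - mse) / k
  sig_c <- (msc - mse) / n
  sig_r / (sig_r + (sig_c + mse) / k)
}

# shared small-cohort simulation for cross-test reuse
make_test_leg <- function(varus = 6, ...) make_leg(varus, ...)
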