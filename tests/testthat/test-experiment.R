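cohort_x <- generate_cohort(cohort_spec(), seed = 17)
wedges_x <- run_conditions(cohort_x)

test_that("the six-condition run produces one plan per knee per condition", {
  expect_identical(nrow(wedges_x), 330L)
  expect_setequal(unique(wedges_x$condition),
                  c("3cm-A", "3cm-B", "3cm-C", "4cm-A", "4cm-B", "4cm-C"))
  expect_true(all(table(wedges_x$condition) == 55))
  expect_true(all(is.na(wedges_x$error)))
  expect_true(all(wedges_x$wedge_mm > 0))
})

test_that("solver failures are recorded per row without aborting", {
  # a knee already in valgus cannot be valgised further under the error policy
  mixed <- cohort_x[1:3, ]
  mixed$varus_deg[2] <- -5
  out <- run_conditions(mixed, heights = 30, hinge_offsets = 5,
                        config = plan_config(already_corrected = "error"))
  expect_identical(nrow(out), 3L)
  expect_true(is.na(out$wedge_mm[out$knee_id == mixed$knee_id[2]]))
  expect_match(out$error[out$knee_id == mixed$knee_id[2]], "already")
  expect_true(all(is.na(out$error[out$knee_id != mixed$knee_id[2]])))
})

test_that("within each knee and height the wedge shrinks as the hinge moves
           medially", {
  wide <- stats::reshape(
    wedges_x[, c("knee_id", "condition", "wedge_mm")],
    idvar = "knee_id", timevar = "condition", direction = "wide")
  expect_true(all(wide$`wedge_mm.3cm-A` > wide$`wedge_mm.3cm-B`))
  expect_true(all(wide$`wedge_mm.3cm-B` > wide$`wedge_mm.3cm-C`))
  expect_true(all(wide$`wedge_mm.4cm-A` > wide$`wedge_mm.4cm-B`))
  expect_true(all(wide$`wedge_mm.4cm-B` > wide$`wedge_mm.4cm-C`))
})

test_that("condition summaries report per-condition moments", {
  s <- condition_summary(wedges_x)
  expect_identical(nrow(s), 6L)
  expect_true(all(s$n == 55))
  # osteotomy height barely matters at a fixed hinge
  expect_lt(abs(s$mean_wedge_mm[s$condition == "3cm-A"] -
                  s$mean_wedge_mm[s$condition == "4cm-A"]), 0.5)
  # all-equal widths give sd 0
  const <- wedges_x[wedges_x$condition == "3cm-A", ]
  const$wedge_mm <- 5
  expect_equal(condition_summary(const)$sd_wedge_mm, 0)
  expect_error(condition_summary(wedges_x[0, ]), "empty")
})

test_that("pairwise differences are paired, linear in the means and match a
           row-wise oracle", {
  pd <- pairwise_differences(wedges_x)
  expect_identical(nrow(pd), 15L) # all unordered pairs of 6 conditions
  get <- function(c1, c2) pd$mean_diff_mm[pd$cond1 == c1 & pd$cond2 == c2]
  # means are linear: diff(A,C) = diff(A,B) + diff(B,C)
  expect_equal(get("3cm-A", "3cm-C"),
               get("3cm-A", "3cm-B") + get("3cm-B", "3cm-C"),
               tolerance = 1e-12)
  # brute-force row subtraction oracle for one pair
  a <- wedges_x[wedges_x$condition == "3cm-A", ]
  c3 <- wedges_x[wedges_x$condition == "3cm-C", ]
  d <- numeric(55)
  for (i in seq_len(55)) {
    d[i] <- a$wedge_mm[a$knee_id == i] - c3$wedge_mm[c3$knee_id == i]
  }
  expect_equal(get("3cm-A", "3cm-C"), mean(d), tolerance = 1e-12)
  expect_equal(pd$rate_ge_threshold_pct[pd$cond1 == "3cm-A" &
                                          pd$cond2 == "3cm-C"],
               100 * mean(abs(d) >= 2), tolerance = 1e-12)
})

test_that("identical conditions give zero difference and zero rate; unpaired
           data are rejected", {
  a <- wedges_x[wedges_x$condition == "3cm-A", ]
  b <- a
  b$condition <- "3cm-B"
  pd <- pairwise_differences(rbind(a, b))
  expect_equal(pd$mean_diff_mm, 0)
  expect_equal(pd$rate_ge_threshold_pct, 0)
  expect_error(pairwise_differences(wedges_x[-1, ]), "not paired")
})

test_that("wedge width carries no bone-length correlation in the default
           cohort", {
  lc <- length_correlations(wedges_x, cohort_x)
  expect_identical(nrow(lc), 12L)
  expect_true(all(abs(lc$r) < 0.3))
  expect_true(all(lc$r >= -1 & lc$r <= 1))
  # y = x exactly gives r = 1 through the same machinery
  fake <- wedges_x[wedges_x$condition == "3cm-A", ]
  fake$wedge_mm <- cohort_x$femoral_length_mm[match(fake$knee_id,
                                                    cohort_x$knee_id)]
  lc1 <- length_correlations(fake, cohort_x)
  expect_equal(lc1$r[lc1$bone == "femoral"], 1, tolerance = 1e-12)
  # constant widths make the correlation undefined
  fake$wedge_mm <- 9
  expect_error(length_correlations(fake, cohort_x), "zero-variance")
})

test_that("wedge widths scale with the overall limb geometry", {
  leg <- make_leg(6)
  base <- plan_osteotomy(leg, 30, 10)
  for (cc in c(0.8, 1.2)) {
    scaled_leg <- make_leg(6, 475 * cc, 372.6 * cc, 79.5 * cc)
    # exact homogeneity when every length scales, condition parameters too
    p <- plan_osteotomy(scaled_leg, 30 * cc, 10 * cc,
                        plan_config(hinge_depth_mm = 15 * cc))
    expect_equal(p$wedge_width, base$wedge_width * cc, tolerance = 1e-9)
  }
  # plateau-only scaling with fixed condition millimetres is first-order
  # homogeneous but not exact (deviations of several percent)
  s0 <- condition_summary(wedges_x)
  for (cc in c(0.8, 1.2)) {
    scaled <- cohort_x
    scaled$plateau_width_mm <- scaled$plateau_width_mm * cc
    s1 <- condition_summary(run_conditions(scaled))
    expect_equal(s1$mean_wedge_mm, s0$mean_wedge_mm * cc,
                 tolerance = 0.1)
  }
})
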