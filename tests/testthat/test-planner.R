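test_that("hinge and entry construction follow the stated offsets", {
  leg <- make_leg(6) # plateau_lateral at (39.75, 0)
  expect_equal(hinge_point(leg, 5, hinge_depth = 0), c(34.75, 0))
  hA <- hinge_point(leg, 5)
  hC <- hinge_point(leg, 15)
  expect_equal(hA - hC, c(10, 0)) # C exactly 10 mm medial of A
  expect_lt(hA[2], 0)             # default depth is distal to the joint line
  expect_error(hinge_point(leg, 0), "inside the plateau")
  expect_error(hinge_point(leg, 80), "inside the plateau")
  expect_error(hinge_point(leg, 5, hinge_depth = -1), "non-negative")

  expect_equal(medial_entry(leg, 30), c(-39.75, -30))
  expect_equal(medial_entry(leg, 40) - medial_entry(leg, 30), c(0, -10))
  flared <- medial_entry(leg, 30, cortex_flare_deg = 10)
  expect_equal(flared[1], -39.75 - 30 * tan(10 * pi / 180))
  expect_error(medial_entry(leg, 0), "positive")
})

test_that("wedge_width is the chord 2 L sin(alpha/2)", {
  expect_equal(wedge_width(75, 0), 0)
  expect_equal(wedge_width(75, 7), 2 * 75 * sin(3.5 * pi / 180)) # 9.157 mm
  expect_equal(wedge_width(150, 7), 2 * wedge_width(75, 7))      # linear in L
  expect_error(wedge_width(-1, 7), "non-negative")
  expect_error(wedge_width(75, 180), "180")
})

test_that("the correction-angle solver reaches the target fraction as a
           fixed point", {
  set.seed(21)
  for (i in 1:20) {
    leg <- make_leg(stats::runif(1, 2, 17),
                    femoral_length = stats::runif(1, 420, 530),
                    tibial_length = stats::runif(1, 320, 420),
                    plateau_width = stats::runif(1, 65, 92),
                    side = sample(c("left", "right"), 1))
    hinge <- hinge_point(leg, sample(c(5, 10, 15), 1))
    a <- solve_correction_angle(leg, hinge)
    expect_gt(a, 0)
    corrected <- apply_correction(leg, hinge, a)
    expect_equal(wbl_fraction(corrected), 0.55, tolerance = 1e-8)
  }
})

test_that("the solver agrees with a brute-force grid sweep to 0.002 deg", {
  set.seed(31)
  for (i in 1:6) {
    leg <- make_leg(stats::runif(1, 3, 15),
                    side = sample(c("left", "right"), 1))
    hinge <- hinge_point(leg, sample(c(5, 15), 1))
    a <- solve_correction_angle(leg, hinge)
    expect_equal(a, oracle_grid_alpha(leg, hinge), tolerance = 2e-3)
  }
})

test_that("already-corrected and unreachable targets follow the error
           contract", {
  valgus <- make_leg(-4)
  hinge <- hinge_point(valgus, 10)
  expect_warning(a <- solve_correction_angle(valgus, hinge), "already")
  expect_identical(a, 0)
  expect_error(
    solve_correction_angle(valgus, hinge, already_corrected = "error"),
    "already")
  severe <- make_leg(17)
  expect_error(
    solve_correction_angle(severe, hinge_point(severe, 15), max_angle = 2),
    "no correction angle")
})

test_that("emitted plans satisfy the chord identity to machine precision", {
  set.seed(41)
  for (i in 1:15) {
    leg <- make_leg(stats::runif(1, 3, 17))
    p <- plan_osteotomy(leg, sample(c(30, 40), 1), sample(c(5, 10, 15), 1))
    expect_equal(
      p$wedge_width,
      2 * p$osteotomy_length * sin(p$correction_angle * pi / 360),
      tolerance = 1e-13)
    expect_gt(p$wedge_width, 0)
    expect_equal(p$achieved_fraction, 0.55, tolerance = 1e-8)
  }
})

test_that("mirrored legs yield identical corrections and wedges", {
  right <- make_leg(9, side = "right")
  left <- make_leg(9, side = "left")
  pr <- plan_osteotomy(right, 30, 10)
  pl <- plan_osteotomy(left, 30, 10)
  expect_equal(pl$correction_angle, pr$correction_angle, tolerance = 1e-10)
  expect_equal(pl$wedge_width, pr$wedge_width, tolerance = 1e-10)
})

test_that("the correction angle is hinge-insensitive while the wedge tracks
           the osteotomy length", {
  leg <- make_leg(6)
  plans <- lapply(c(5, 10, 15), function(d) plan_osteotomy(leg, 30, d))
  alphas <- vapply(plans, `[[`, 0, "correction_angle")
  expect_lt(max(alphas) - min(alphas), 0.3)
  # the hinge moving medially shortens the cut, so the wedge shrinks
  w <- vapply(plans, `[[`, 0, "wedge_width")
  L <- vapply(plans, `[[`, 0, "osteotomy_length")
  expect_true(all(diff(w) < 0))
  expect_true(all(diff(L) < 0))
})

test_that("wedge width grows with target fraction and with varus", {
  leg <- make_leg(6)
  w_by_target <- vapply(c(0.50, 0.55, 0.60, 0.65), function(tf) {
    plan_osteotomy(leg, 30, 10, plan_config(target_fraction = tf))$wedge_width
  }, 0)
  expect_true(all(diff(w_by_target) > 0))
  w_by_varus <- vapply(c(3, 6, 9, 12, 17), function(v) {
    plan_osteotomy(make_leg(v), 30, 10)$wedge_width
  }, 0)
  expect_true(all(diff(w_by_varus) > 0))
})

test_that("configuration knobs act as documented", {
  leg <- make_leg(6)
  base <- plan_osteotomy(leg, 30, 10)
  kerf <- plan_osteotomy(leg, 30, 10, plan_config(saw_kerf_mm = 1.5))
  expect_equal(kerf$wedge_width, base$wedge_width + 1.5)
  # condition labels
  expect_identical(base$condition_label, "3cm-B")
  expect_identical(plan_osteotomy(leg, 40, 15)$condition_label, "4cm-C")
  expect_identical(plan_osteotomy(leg, 35, 7)$condition_label, "h35mm-d7mm")
})

test_that("a wedge planned at one hinge under-corrects when executed at a
           more lateral hinge", {
  leg <- make_leg(6)
  planned <- plan_osteotomy(leg, 40, 15)
  achieved <- achieved_fraction(leg, planned$wedge_width, 40, 5)
  expect_lt(achieved, 0.55)
  # and the planned condition itself reproduces its own target
  expect_equal(achieved_fraction(leg, planned$wedge_width, 40, 15), 0.55,
               tolerance = 1e-8)
})
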