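test_that("cumulative projection follows the geometric partial sum", {
  expect_equal(project_cumulative_benefits(projection_params(7, 0, 5)),
               c("5" = 35))
  expect_equal(project_cumulative_benefits(projection_params(0, 0.1, c(5, 10))),
               c("5" = 0, "10" = 0))
  # geometric series: with q = 1 + g, cumulative(T) = b (q^T - 1)/(q - 1)
  p <- projection_params(8.377, -0.0899, c(5, 20))
  q <- 1 - 0.0899
  expect_equal(unname(project_cumulative_benefits(p)),
               8.377 * c((q^5 - 1), (q^20 - 1)) / (q - 1), tolerance = 1e-12)
  expect_equal(unname(project_cumulative_benefits(p)), c(35.0, 79.0),
               tolerance = 0.1)
})

test_that("invalid projection parameters are rejected", {
  expect_error(projection_params(-1, 0), class = "bioecon_invalid_parameter")
  expect_error(projection_params(1, -1), class = "bioecon_invalid_parameter")
  expect_error(projection_params(1, 0, c(0, 5)), class = "bioecon_invalid_horizon")
  expect_error(projection_params(1, 0, c(10, 5)), class = "bioecon_invalid_horizon")
  expect_error(projection_params(1, 0, c(2.5)), class = "bioecon_invalid_horizon")
})

test_that("calibration hits the g = 0 branch on exactly proportional anchors", {
  p <- calibrate_projection(list(c(5, 35), c(20, 140)))
  expect_identical(p$g, 0)
  expect_equal(p$b, 7)
  expect_equal(unname(project_cumulative_benefits(projection_params(7, 0, c(5, 20)))),
               c(35, 140))
})

test_that("calibration on the printed 5/20-year anchors implies a decelerating stream", {
  p <- calibrate_projection(list(c(5, 35), c(20, 79)))
  expect_equal(p$g, -0.090, tolerance = 0.005)
  expect_equal(p$b, 8.38, tolerance = 0.05)
  fwd <- project_cumulative_benefits(projection_params(p$b, p$g, c(5, 20)))
  expect_equal(unname(fwd), c(35, 79), tolerance = 1e-6)
})

test_that("anchors with shrinking cumulative totals are infeasible", {
  expect_error(calibrate_projection(list(c(5, 35), c(20, 30))),
               class = "bioecon_infeasible_anchors")
  expect_error(calibrate_projection(list(c(5, 35), c(5, 40))),
               class = "bioecon_invalid_horizon")
})

test_that("property: calibration recovers known (b, g) from their own anchors", {
  set.seed(161803)
  for (i in 1:200) {
    b <- runif(1, 1, 100)
    g <- runif(1, -0.2, 0.2)
    truth <- projection_params(b, g, c(5, 20))
    cum <- project_cumulative_benefits(truth)
    p <- calibrate_projection(list(c(5, cum[["5"]]), c(20, cum[["20"]])))
    expect_equal(p$b, b, tolerance = 1e-6)
    expect_equal(p$g, g, tolerance = 1e-6)
  }
})

test_that("cumulative totals are nondecreasing and linear in T at g = 0", {
  p <- projection_params(3.5, 0, c(1, 4, 9, 30))
  expect_equal(unname(project_cumulative_benefits(p)), 3.5 * c(1, 4, 9, 30))
  pg <- projection_params(5, -0.15, c(1, 5, 10, 20, 40))
  cum <- project_cumulative_benefits(pg)
  expect_true(all(diff(cum) > 0))
})

test_that("per-sector projections aggregate and share out correctly", {
  # identical sectors split 50/50 at every horizon
  ps <- project_by_sector(c(a = 4, b = 4), 0.05, c(5, 10, 20))
  expect_equal(unname(ps$shares), matrix(50, 2, 3), tolerance = 1e-12)
  expect_equal(unname(ps$totals), 2 * 4 * sapply(c(5, 10, 20), function(T) (1.05^T - 1) / 0.05))

  # a flat sector gains share against a declining one
  ps2 <- project_by_sector(c(flat = 5, declining = 5),
                           c(flat = 0, declining = -0.1), c(5, 10, 20))
  expect_true(all(diff(ps2$shares["flat", ]) > 0))

  # equal growth preserves the initial 53/40/7 split at every horizon
  ps3 <- project_by_sector(c(agriculture = 53, `R&D` = 40, other = 7),
                           -0.09, c(5, 10, 20))
  for (h in colnames(ps3$shares)) {
    expect_equal(unname(ps3$shares[, h]), c(53, 40, 7), tolerance = 1e-9)
  }

  expect_error(project_by_sector(c(a = 1, b = 2), c(a = 0, z = 0)),
               class = "bioecon_alignment_error")
})
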