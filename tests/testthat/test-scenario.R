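test_that("default scenario carries the appraisal's stated assumptions", {
  sc <- scenario()
  expect_equal(sc$investment_total, 20)
  expect_equal(sc$allocation, c("R&D" = 0.5, "agriculture" = 0.5))
  expect_equal(sc$productivity_gain, 0.10)
  expect_equal(sc$linkage_delta, 0)
})

test_that("final demand places the split investment and sums exactly", {
  labels <- default_sector_labels(27)
  F <- build_final_demand(scenario(), labels)
  expect_equal(unname(F$F["R&D"]), 10)
  expect_equal(unname(F$F["agriculture"]), 10)
  expect_equal(sum(F$F), 20)
  expect_equal(sum(F$F != 0), 2)

  Fa <- build_final_demand(scenario(allocation = c(agriculture = 1)), labels)
  expect_equal(unname(Fa$F["agriculture"]), 20)
  expect_equal(sum(Fa$F), 20)
})

test_that("bad allocations and unknown sectors are rejected", {
  expect_error(scenario(allocation = c("R&D" = 0.5, "agriculture" = 0.4)),
               class = "bioecon_allocation_error")
  expect_error(scenario(allocation = c("R&D" = -0.2, "agriculture" = 1.2)),
               class = "bioecon_allocation_error")
  expect_error(build_final_demand(scenario(allocation = c(nonexistent = 1)),
                                  default_sector_labels(27)),
               class = "bioecon_label_error")
})

test_that("productivity gain scales target columns by 1/(1+g)", {
  A <- compute_technical_coefficients(e2())
  A2 <- apply_productivity_gain(A, "s1", 0.10)
  expect_equal(unname(A2$A[, 1]), c(0.1, 0.3) / 1.1, tolerance = 1e-12)
  expect_equal(unname(A2$A[, 1]), c(0.090909, 0.272727), tolerance = 1e-5)
  expect_equal(A2$A[, 2], A$A[, 2])
  expect_identical(apply_productivity_gain(A, "s1", 0), A)
  # adjugate oracle: det(I-A') = 0.7, column-1 multiplier (0.8 + 0.272727)/0.7
  m2 <- output_multipliers(leontief_inverse(A2))
  expect_equal(unname(m2[1]), (0.8 + 0.3 / 1.1) / 0.7, tolerance = 1e-9)
  expect_equal(unname(m2[1]), 1.532468, tolerance = 1e-6)
  expect_error(apply_productivity_gain(A, "nope", 0.1), class = "bioecon_label_error")
})

test_that("linkage strengthening raises coefficients and multipliers, or refuses", {
  A <- compute_technical_coefficients(e2())
  expect_identical(strengthen_linkages(A, "s2", "s1", 0), A)
  A2 <- strengthen_linkages(A, "s2", "s1", 0.05)
  expect_equal(unname(A2$A[2, 1]), 0.35)
  # adjugate oracle: det(I-A') = 0.9*0.8 - 0.1*0.35 = 0.685
  m2 <- output_multipliers(leontief_inverse(A2))
  expect_equal(unname(m2[1]), (0.8 + 0.35) / 0.685, tolerance = 1e-9)
  expect_equal(unname(m2[1]), 1.678832, tolerance = 1e-6)
  # 0.1 + 0.3 + 0.7 pushes column 1's sum past 1: rejected, input unchanged
  expect_error(strengthen_linkages(A, "s2", "s1", 0.7),
               class = "bioecon_nonproductive")
  expect_equal(unname(A$A[2, 1]), 0.3)
})

test_that("base and adjusted cases diverge as the exact-fraction oracle predicts", {
  tb <- e2(labels = c("agriculture", "R&D"))
  sc <- scenario(allocation = c("R&D" = 0.5, "agriculture" = 0.5),
                 productivity_gain = 0.10,
                 productivity_targets = "agriculture",
                 linkage_targets = character(0), linkage_delta = 0)
  res <- run_base_and_adjusted(tb, sc)
  expect_equal(res$base$total, c(13.043478, 17.391304), tolerance = 1e-5)
  # L'F with column 1 of A scaled by 1/1.1: det(I-A') = 7/10,
  # totals (exact fractions) 90/7 and 1300/77
  expect_equal(res$adjusted$total, c(90 / 7, 1300 / 77), tolerance = 1e-9)
  expect_equal(res$incremental, res$adjusted$total - res$base$total,
               ignore_attr = TRUE)
})

test_that("a do-nothing scenario leaves base and adjusted identical", {
  tb <- generate_economy(27, seed = 3)
  sc <- scenario(productivity_gain = 0, linkage_delta = 0)
  res <- run_base_and_adjusted(tb, sc)
  expect_equal(res$base$total, res$adjusted$total, tolerance = 1e-12)
  expect_true(all(abs(res$incremental) < 1e-12))
})

test_that("property: gains lower L entries, linkage deltas raise them", {
  set.seed(1234)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    cm <- coefficient_matrix(random_productive_A(n, cap = 0.7))
    L0 <- leontief_inverse(cm)$L
    tgt <- sample(cm$labels, 2)
    Lg <- leontief_inverse(apply_productivity_gain(cm, tgt, 0.15))$L
    expect_true(all(Lg <= L0 + 1e-12))
    Ll <- leontief_inverse(strengthen_linkages(cm, cm$labels[1],
                                               cm$labels[-1], 0.02))$L
    expect_true(all(Ll >= L0 - 1e-12))
  }
})

test_that("scenario files round-trip through YAML and JSON, rejecting unknown keys", {
  cfg <- list(investment_total = 30,
              allocation = list("R&D" = 0.25, agriculture = 0.75),
              productivity_gain = 0.2,
              linkage = list(source = "R&D", targets = list("education"), delta = 0.01),
              discount_rate = 0.03, horizons = c(5, 10))
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, ypath)
  sc <- read_scenario(ypath)
  expect_equal(sc$investment_total, 30)
  expect_equal(sum(sc$allocation), 1)
  expect_equal(sc$linkage_delta, 0.01)
  expect_equal(attr(sc, "discount_rate"), 0.03)

  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jpath, auto_unbox = TRUE)
  sj <- read_scenario(jpath)
  expect_equal(sj$investment_total, sc$investment_total)
  expect_equal(sj$productivity_gain, 0.2)

  bad <- c(cfg, list(mystery_knob = 1))
  bpath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, bpath)
  expect_error(read_scenario(bpath), class = "bioecon_invalid_parameter")
})
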