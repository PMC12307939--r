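test_that("a 1-sector economy is forced by the accounting identities", {
  tb <- generate_economy(1, seed = 0)
  z <- tb$Z[1, 1]; x <- tb$x[[1]]
  expect_equal(tb$f[[1]], x - z)
  expect_equal(tb$va[[1]], x - z)
  expect_lt(z / x, 0.9)
})

test_that("generated economies pass the validator with zero violations", {
  for (seed in c(1, 7, 42)) {
    tb <- generate_economy(27, seed = seed, spectral_cap = 0.9)
    expect_identical(nrow(validate_economy(tb)), 0L)
    A <- compute_technical_coefficients(tb)
    expect_lt(spectral_radius(A$A), 0.9)
  }
})

test_that("generation is deterministic in the seed and sensitive to it", {
  a <- generate_economy(12, seed = 5)
  b <- generate_economy(12, seed = 5)
  expect_identical(a, b)
  d <- generate_economy(12, seed = 6)
  expect_false(isTRUE(all.equal(a$Z, d$Z)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_economy(8, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("default 27-sector nomenclature covers the appraised sectors", {
  lab <- generate_economy(27, seed = 1)$labels
  expect_true(all(c("agriculture", "fishing", "manufacturing", "R&D",
                    "education", "services") %in% lab))
  expect_false(anyDuplicated(lab) > 0)
})

test_that("invalid generator arguments are rejected", {
  expect_error(generate_economy(0), class = "bioecon_invalid_size")
  expect_error(generate_economy(-3), class = "bioecon_invalid_size")
  expect_error(generate_economy(5, spectral_cap = 1), class = "bioecon_invalid_parameter")
  expect_error(generate_economy(5, spectral_cap = 0), class = "bioecon_invalid_parameter")
  expect_error(generate_economy(3, labels = c("a", "a", "b")),
               class = "bioecon_invalid_parameter")
})

test_that("validator reports specific violations on corrupted tables", {
  tb <- e2()
  expect_identical(nrow(validate_economy(tb)), 0L)

  bad <- tb; bad$Z[1, 1] <- -1
  v <- validate_economy(bad)
  expect_true("negative_flow" %in% v$rule)

  # column-1 sum of Z (40) exceeds the claimed output 35 -> negative value added
  bad2 <- flow_table(Z = tb$Z, x = c(35, 200), f = tb$f, va = c(35 - 40, 140),
                     labels = tb$labels)
  v2 <- validate_economy(bad2)
  expect_true("negative_value_added" %in% v2$rule)

  # broken identity is flagged per sector
  bad3 <- tb; bad3$f[1] <- 999
  v3 <- validate_economy(bad3)
  expect_true(any(v3$rule == "row_identity" & v3$sector == "s1"))
})

test_that("dimension mismatches raise structural errors, not violation rows", {
  expect_error(flow_table(Z = matrix(0, 2, 2), x = 1:3, f = 1:2, va = 1:2),
               class = "bioecon_structural_error")
  expect_error(flow_table(Z = matrix(0, 2, 3), x = 1:2, f = 1:2, va = 1:2),
               class = "bioecon_structural_error")
})

test_that("household closure data is generated on request and is consistent", {
  tb <- generate_economy(10, seed = 11, household = TRUE)
  expect_false(is.null(tb$household))
  expect_length(tb$household$income, 10)
  expect_true(all(tb$household$income <= tb$va + 1e-12))
  expect_equal(sum(tb$household$consumption), 0.9 * sum(tb$household$income))
  expect_identical(nrow(validate_economy(tb)), 0L)
})

test_that("flow-table CSV dialect round-trips exactly enough for analysis", {
  tb <- generate_economy(6, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_flow_table(tb, path)
  back <- read_flow_table(path)
  expect_identical(back$labels, tb$labels)
  expect_equal(back$Z, tb$Z, tolerance = 1e-12)
  expect_equal(back$x, tb$x, tolerance = 1e-12)
  expect_identical(nrow(validate_economy(back)), 0L)
  # header layout: sector, n names, final_demand, total_output; value_added last
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(gsub('"', "", hdr[1]), "sector")
  expect_identical(gsub('"', "", utils::tail(hdr, 2)), c("final_demand", "total_output"))
  last <- utils::tail(readLines(path), 1)
  expect_match(last, "^\"?value_added")
})

property_seeds <- 1:100

test_that("property: every generated economy validates and respects the spectral cap", {
  for (seed in property_seeds) {
    n <- (seed %% 30) + 1
    cap <- c(0.5, 0.7, 0.9)[(seed %% 3) + 1]
    tb <- generate_economy(n, seed = seed, spectral_cap = cap)
    expect_identical(nrow(validate_economy(tb)), 0L)
    A <- sweep(tb$Z, 2, tb$x, "/")
    expect_lt(spectral_radius(A), cap)
  }
})
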