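# Scans here use the small gentle instance so each grid point is cheap; the
# full-size k_Deg x k_b scan runs in the acceptance suite.

test_that("the grid cell at the baseline parameter values has fit zero", {
  p <- oracle_params()
  baseline <- dlgradient:::as_normalized_profile(p, window = 12)
  grid <- sensitivity_scan(p, "k_Deg", c(0.1, p$k_Deg, 0.5),
                          "k_b", c(0.005, p$k_b), baseline = baseline,
                          window = 12)
  expect_equal(dim(grid$fit_matrix), c(2, 3))
  expect_equal(grid$fit_matrix[grid$values_y == p$k_b,
                               grid$values_x == p$k_Deg], 0)
  expect_true(all(grid$fit_matrix >= 0))
})

test_that("infeasible geometry becomes an error cell, not a failure", {
  p <- oracle_params()
  baseline <- dlgradient:::as_normalized_profile(p, window = 12)
  grid <- sensitivity_scan(p, "r", c(3, 60), "Er", c(102.4, 90),
                          baseline = baseline, window = 12)
  expect_equal(dim(grid$fit_matrix), c(2, 2))
  bad <- grid$values_x == 60
  expect_true(all(is.na(grid$fit_matrix[, bad])))
  expect_true(all(grepl("larger than compartment", grid$status[, bad])))
  expect_true(all(!is.na(grid$fit_matrix[, !bad])))
})

test_that("unknown scan parameters are rejected", {
  p <- oracle_params()
  expect_error(sensitivity_scan(p, "k_Dg", 1, "k_b", 1, baseline = NULL),
               "unknown parameter")
})

test_that("a row of the grid reproduces the single-parameter sweep", {
  p <- oracle_params()
  baseline <- dlgradient:::as_normalized_profile(p, window = 12)
  kdeg_vals <- c(0.1, 0.2, 0.5)
  grid <- sensitivity_scan(p, "k_Deg", kdeg_vals, "k_b", p$k_b,
                          baseline = baseline, window = 12)
  sweep <- vapply(kdeg_vals, function(v) {
    prof <- dlgradient:::as_normalized_profile(set_params(p, k_Deg = v),
                                               window = 12)
    fit_distance(prof, baseline)
  }, numeric(1))
  expect_equal(as.numeric(grid$fit_matrix[1, ]), sweep)
})

test_that("repeated scans are bitwise identical", {
  p <- oracle_params()
  baseline <- dlgradient:::as_normalized_profile(p, window = 12)
  g1 <- sensitivity_scan(p, "k_Deg", c(0.1, 0.4), "k_b", c(0.005, 0.02),
                        baseline = baseline, window = 12)
  g2 <- sensitivity_scan(p, "k_Deg", c(0.1, 0.4), "k_b", c(0.005, 0.02),
                        baseline = baseline, window = 12)
  expect_identical(g1$fit_matrix, g2$fit_matrix)
})

test_that("contour levels are evenly spaced from zero to the grid maximum", {
  m <- matrix(c(0, 0.012, 0.02, 0.035), 2)
  expect_equal(contour_levels(m, 0.01), c(0, 0.01, 0.02, 0.03))
  expect_equal(contour_levels(m, 0.011), c(0, 0.011, 0.022, 0.033))
  expect_error(contour_levels(m, 0), "positive")
  g <- structure(list(fit_matrix = m), class = "dl_sensitivity")
  expect_equal(contour_levels(g, 0.01), c(0, 0.01, 0.02, 0.03))
})

test_that("sensitivity grids round-trip key content through TSV", {
  p <- oracle_params()
  baseline <- dlgradient:::as_normalized_profile(p, window = 12)
  grid <- sensitivity_scan(p, "k_Deg", c(0.1, 0.4), "k_b", c(0.005, 0.02),
                          baseline = baseline, window = 12)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_sensitivity_tsv(grid, tmp)
  df <- read.delim(tmp)
  expect_equal(nrow(df), 4)
  expect_equal(sort(df$fit), sort(as.numeric(grid$fit_matrix)))
})
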