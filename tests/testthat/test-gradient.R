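test_that("ventral window extraction keeps the 30 nuclei nearest the
           midline, ordered by signed position", {
  # symmetric synthetic ring profile, compartment 1 at theta = 0
  n <- 92
  th <- build_geometry(load_parameter_set("mel_adjusted"))$theta
  raw <- exp(-4 * th^2)
  w <- extract_ventral_window(raw, 30)
  expect_length(w$values, 30)
  expect_identical(w$positions, -15:14)
  # mirror symmetry propagates: position -k equals +k
  for (k in 1:14)
    expect_equal(w$values[w$positions == -k], w$values[w$positions == k])
  # identity window returns the full ring
  expect_length(extract_ventral_window(raw, 92)$values, 92)
  expect_error(extract_ventral_window(raw[1:30], 31), "exceeds")
})

test_that("extract + normalize commute with mirror reflection", {
  # odd window, so the window position set is itself mirror-symmetric
  n <- 92
  set.seed(11)
  raw <- runif(n)
  # reflection about theta = 0: index j -> n + 2 - j (compartment 1 fixed)
  refl <- raw[c(1, n:2)]
  a <- normalize_profile(extract_ventral_window(raw, 31))$values
  b <- normalize_profile(extract_ventral_window(refl, 31))$values
  pos <- -15:15
  for (k in 0:15) {
    expect_equal(b[pos == k], a[pos == -k])
    expect_equal(b[pos == -k], a[pos == k])
  }
})

test_that("min-max normalization maps onto [0,1] and is idempotent", {
  p <- normalize_profile(gradient_profile(c(2, 4, 6)))
  expect_equal(p$values, c(0, 0.5, 1))
  expect_true(p$normalized)
  expect_equal(normalize_profile(p)$values, p$values)
  expect_error(normalize_profile(gradient_profile(c(5, 5, 5))), "constant")
})

test_that("peak normalization preserves the baseline", {
  p <- normalize_profile(gradient_profile(c(1, 2, 4)), method = "peak")
  expect_equal(p$values, c(0.25, 0.5, 1))
  expect_equal(normalize_profile(p, method = "peak")$values, p$values)
})

test_that("fit distance is the Euclidean metric on profiles", {
  expect_equal(fit_distance(rep(0.3, 30), rep(0.3, 30)), 0)
  expect_equal(fit_distance(rep(0, 4), rep(1, 4)), 2)
  expect_equal(fit_distance(rep(0, 30), rep(1, 30)), sqrt(30))
  expect_error(fit_distance(rep(0, 30), rep(1, 29)), "lengths")
  # metric axioms on random triples
  set.seed(5)
  for (i in 1:20) {
    a <- runif(30); b <- runif(30); c <- runif(30)
    expect_gte(fit_distance(a, b), 0)
    expect_equal(fit_distance(a, b), fit_distance(b, a))
    expect_lte(fit_distance(a, c),
               fit_distance(a, b) + fit_distance(b, c) + 1e-12)
  }
})

test_that("confidence intervals match the t-distribution construction", {
  set.seed(9)
  reps <- matrix(rnorm(30 * 5, mean = 0.5, sd = 0.1), 30, 5)
  ci <- confidence_interval(reps, 0.99)
  # independent route: stats::t.test per position
  for (j in c(1, 15, 30)) {
    tt <- stats::t.test(reps[j, ], conf.level = 0.99)
    expect_equal(ci$lower[j], tt$conf.int[1])
    expect_equal(ci$upper[j], tt$conf.int[2])
  }
  # identical replicates give zero-width intervals
  same <- matrix(rep(seq(0, 1, length.out = 30), 4), 30, 4)
  ci0 <- confidence_interval(same, 0.99)
  expect_equal(ci0$lower, ci0$upper)
  # wider level contains narrower level
  ci95 <- confidence_interval(reps, 0.95)
  expect_true(all(ci$lower <= ci95$lower & ci$upper >= ci95$upper))
  expect_error(confidence_interval(matrix(1:30, 30, 1)), "at least 2")
})

test_that("compare_profiles scores a simulation against a reference", {
  p <- oracle_params()
  sim <- simulate_final_cycle(p)
  self <- compare_profiles(sim, extract_ventral_window(sim, 12),
                           window = 12)
  expect_equal(self$fit, 0)
  # a cohort reference carries a CI; the generating profile stays inside it
  co <- generate_cohort(extract_ventral_window(sim, 12), n_embryos = 5,
                        noise_sd = 0.02, seed = 3)
  rep_cmp <- compare_profiles(sim, cohort_profile(co), window = 12)
  expect_true(mean(rep_cmp$inside_ci) > 0.8)
  # distinct parameter sets give distinct shapes
  gyn_ref <- dlgradient:::as_normalized_profile("gyn_3")
  cross <- compare_profiles("mel_adjusted", gyn_ref)
  expect_gt(cross$fit, 0)
})

test_that("profiles round-trip through TSV", {
  prof <- gradient_profile(seq(0, 1, length.out = 30), normalized = TRUE)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_profile_tsv(prof, tmp)
  back <- read_profile_tsv(tmp, normalized = TRUE)
  expect_equal(back$values, prof$values)
  expect_identical(back$positions, prof$positions)
})
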