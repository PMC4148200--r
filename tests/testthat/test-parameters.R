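test_that("packaged fixtures carry the published values", {
  mel <- load_parameter_set("mel_adjusted")
  expect_equal(mel$Er, 102.4)
  expect_equal(mel$Gamma, 2)
  expect_equal(mel$k_i, 4)
  expect_equal(mel$k_e, 1)
  expect_equal(mel$n, 92)
  expect_equal(mel$t, 65)

  gyn <- load_parameter_set("gyn_3")
  expect_equal(gyn$Er, 117)
  expect_equal(gyn$r, 5.45)
  expect_equal(gyn$n, 72)
  expect_equal(gyn$t, 86)

  orig <- load_parameter_set("mel_original")
  expect_equal(orig$R, 15340)
  expect_equal(orig$xi, 2.38)
  expect_equal(orig$k_i, 1.97)

  expect_length(list_parameter_sets(), 30)
})

test_that("unknown fixture labels error and list the valid ones", {
  expect_error(load_parameter_set("nosuch"), "mel_adjusted")
})

test_that("every fixture round-trips through serialization unchanged", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  fields <- dlgradient:::PARAM_FIELDS
  for (label in list_parameter_sets()) {
    p <- load_parameter_set(label)
    write_parameter_set(p, tmp)
    q <- load_parameter_set(tmp)
    expect_identical(unclass(p)[fields], unclass(q)[fields], info = label)
  }
})

test_that("parameter validation rejects inconsistent sets", {
  mel <- load_parameter_set("mel_adjusted")
  expect_error(set_params(mel, Eh = 200), "Eh")
  expect_error(set_params(mel, k_Deg = -1), "non-negative")
  expect_error(set_params(mel, nope = 3), "unknown parameter")
})

test_that("Toll dissociation rate peaks at the ventral midline, is even,
           monotone and linear in its amplitude", {
  for (label in c("mel_original", "mel_adjusted", "bus_3", "sec_5")) {
    p <- load_parameter_set(label)
    expect_equal(toll_dissociation_rate(0, p$R, p$S, p$xi), p$R)
    th <- seq(0, pi, length.out = 200)
    kd <- toll_dissociation_rate(th, p$R, p$S, p$xi)
    expect_equal(toll_dissociation_rate(-th, p$R, p$S, p$xi), kd)
    expect_true(all(diff(kd) <= 1e-12))           # non-increasing in |theta|
    expect_equal(toll_dissociation_rate(th, 2 * p$R, p$S, p$xi), 2 * kd)
  }
  expect_error(toll_dissociation_rate(0, -1, 4000, 2.5), "non-negative")
  expect_error(toll_dissociation_rate(4, 1, 1, 2), "theta")
})

test_that("arc-length rescaling of R reproduces the published adjusted values
           and is homogeneous", {
  expect_identical(scale_R_by_arclength(15000, 21, 17), 12142L)
  expect_identical(scale_R_by_arclength(15000, 21, 27), 19285L)
  expect_identical(scale_R_by_arclength(15000, 21, 26), 18571L)
  expect_identical(scale_R_by_arclength(15000, 21, 21), 15000L)
  # degree-1 homogeneity in R and invariance under joint percent scaling
  expect_identical(scale_R_by_arclength(30000, 21, 17),
                   as.integer(trunc(2 * 15000 * 17 / 21)))
  expect_identical(scale_R_by_arclength(15000, 42, 34), 12142L)
  expect_error(scale_R_by_arclength(15000, 0, 17), "positive")
})

test_that("random parameter sampling is deterministic, bounded and validated", {
  rng <- list(k_Deg = c(0.3, 5), k_b = c(0.005, 0.05), Gamma = c(0.01, 2))
  expect_length(sample_parameter_sets(rng, 0, seed = 1), 0)
  a <- sample_parameter_sets(rng, 5, seed = 42)
  b <- sample_parameter_sets(rng, 5, seed = 42)
  expect_identical(lapply(a, unclass), lapply(b, unclass))
  many <- sample_parameter_sets(rng, 1000, seed = 7)
  for (f in names(rng)) {
    v <- vapply(many, `[[`, numeric(1), f)
    expect_true(all(v >= rng[[f]][1] & v <= rng[[f]][2]))
  }
  expect_error(sample_parameter_sets(list(k_b = c(2, 1)), 3, seed = 1),
               "low <= high")
})
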