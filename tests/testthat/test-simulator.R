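test_that("rhs is spatially uniform when Toll activation is flat", {
  # S = 0 makes k_D constant; a uniform state must stay uniform
  p <- set_params(load_parameter_set("mel_adjusted"), S = 0, n = 10)
  g <- build_geometry(p)
  st <- list(d = rep(3, 10), c = rep(5, 10), dc = rep(7, 10),
             dn = rep(2, 10))
  dv <- dl_rhs(st, 0, p, g)
  for (f in c("d", "c", "dc", "dn"))
    expect_equal(diff(range(dv[[f]])), 0)
})

test_that("rhs conserves total Dl exactly at the derivative level", {
  for (seed in 1:5) {
    p <- load_parameter_set("mel_adjusted")
    g <- build_geometry(p)
    st <- random_state(g$n_compartments, seed)
    dv <- dl_rhs(st, 0, p, g)
    ddt_total <- sum((dv$d + dv$dc) * g$V_cyt) + sum(dv$dn * g$V_nuc)
    scale <- sum(abs(dv$d) * g$V_cyt)
    expect_lt(abs(ddt_total) / scale, 1e-12)
  }
})

test_that("with no transport, compartments are decoupled", {
  p <- set_params(load_parameter_set("mel_adjusted"), Gamma = 0, n = 12)
  g <- build_geometry(p)
  st <- random_state(12, 1)
  dv0 <- dl_rhs(st, 0, p, g)
  st$d[5] <- st$d[5] + 10   # perturb one compartment only
  dv1 <- dl_rhs(st, 0, p, g)
  expect_equal(dv1$c[-5], dv0$c[-5])
  expect_equal(dv1$d[-5], dv0$d[-5])
  expect_equal(dv1$dn[-5], dv0$dn[-5])
  expect_false(isTRUE(all.equal(dv1$d[5], dv0$d[5])))
})

test_that("rhs rejects non-finite states with a compartment index", {
  p <- load_parameter_set("mel_adjusted")
  g <- build_geometry(p)
  st <- random_state(g$n_compartments, 1)
  st$dc[7] <- NaN
  expect_error(dl_rhs(st, 0, p, g), "compartment 7")
})

test_that("compiled and reference right-hand sides integrate identically", {
  p <- oracle_params()
  a <- simulate_final_cycle(p, compiled = TRUE)
  b <- simulate_final_cycle(p, compiled = FALSE)
  for (f in c("d", "c", "dc", "dn"))
    expect_equal(a$final_state[[f]], b$final_state[[f]], tolerance = 1e-7)
  # and on a full-size stiff instance
  pm <- load_parameter_set("mel_adjusted")
  am <- simulate_final_cycle(pm, compiled = TRUE)
  bm <- simulate_final_cycle(pm, compiled = FALSE)
  expect_equal(am$raw_nuclear_profile, bm$raw_nuclear_profile,
               tolerance = 1e-6)
})

test_that("the nuclear profile is mirror-symmetric about the ventral midline", {
  sim <- simulate_final_cycle(load_parameter_set("mel_adjusted"))
  dn <- sim$raw_nuclear_profile
  n <- length(dn)
  # compartment 1 sits at theta = 0; j and n+2-j are mirror images
  expect_lt(max(abs(dn[2:(n / 2)] - dn[n:(n / 2 + 2)])), 1e-9 * max(dn))
})

test_that("the gradient peaks at the ventral midline plateau", {
  sim <- simulate_final_cycle(load_parameter_set("mel_adjusted"))
  dn <- sim$raw_nuclear_profile
  th <- sim$geometry$theta
  # high transport gives a flat top: the midline value is within 1% of the
  # maximum and the argmax lies inside the central plateau (|theta| < 0.2)
  expect_gt(dn[1], 0.99 * max(dn))
  expect_lt(abs(th[which.max(dn)]), 0.2)
  expect_gt(dn[1], dn[which.min(abs(abs(th) - pi / 2))[1]])
})

test_that("total Dl bookkeeping: zero state, additivity, trajectory
           conservation", {
  p <- load_parameter_set("mel_adjusted")
  g <- build_geometry(p)
  zero <- list(d = numeric(92), c = numeric(92), dc = numeric(92),
               dn = numeric(92))
  expect_equal(total_dl(zero, g), 0)
  st <- random_state(92, 3)
  half <- lapply(st, function(v) { v[47:92] <- 0; v })
  other <- lapply(st, function(v) { v[1:46] <- 0; v })
  expect_equal(total_dl(st, g), total_dl(half, g) + total_dl(other, g))
  sim <- simulate_final_cycle(p)
  expect_lt(abs(sim$diagnostics$total_dl_drift), 1e-6)
})

test_that("effective diffusion scales with arc width squared and embryo
           size", {
  g <- build_geometry(load_parameter_set("mel_adjusted"))
  expect_equal(effective_diffusion_coefficient(0, g), 0)
  g2 <- g; g2$w_arc <- 2 * g$w_arc
  expect_equal(effective_diffusion_coefficient(2, g2),
               4 * effective_diffusion_coefficient(2, g))
  # larger embryo radius at the same Gamma and n -> larger D
  gb <- build_geometry(load_parameter_set("gyn_3"))   # Er = 117
  gs <- build_geometry(set_params(load_parameter_set("gyn_3"), Er = 102.4))
  expect_gt(effective_diffusion_coefficient(2, gb),
            effective_diffusion_coefficient(2, gs))
})

test_that("division re-partitioning conserves amounts on the ring", {
  W <- dlgradient:::ring_overlap_matrix(23, 33)
  expect_equal(colSums(W), rep(1, 23), tolerance = 1e-12)
  amt <- matrix(runif(3 * 23), 3, 23)
  out <- dlgradient:::repartition_ring(amt, 23, 33)
  expect_equal(rowSums(out), rowSums(amt), tolerance = 1e-12)
  # identity when the ring is unchanged
  expect_equal(dlgradient:::repartition_ring(amt, 23, 23), amt,
               tolerance = 1e-12)
})

test_that("multicycle simulation conserves Dl within and across cycles", {
  p <- load_parameter_set("mel_adjusted")
  mc <- simulate_multicycle(p)
  expect_equal(vapply(mc, function(r) r$cycle, numeric(1)), 10:14)
  expect_identical(mc[[5]]$geometry$n_compartments, 92L)
  for (r in mc) {
    expect_equal(r$total_dl_end, r$total_dl_start,
                 tolerance = 1e-6)
    if (!is.null(r$total_dl_after_division))
      expect_equal(r$total_dl_after_division, r$total_dl_end,
                   tolerance = 1e-12)
  }
})

test_that("early-cycle nuclear radii do not change the final gradient shape", {
  p <- load_parameter_set("mel_adjusted")
  base <- simulate_multicycle(p)
  prof <- default_radius_profile(p$r, 10, 14)
  up <- prof
  early <- up$cycle < 14
  up$r_start[early] <- up$r_start[early] * 1.25
  up$r_end[early] <- up$r_end[early] * 1.25
  pert <- simulate_multicycle(p, profile = up)
  a <- minmax(extract_ventral_window(base[[5]]$raw_nuclear_profile)$values)
  b <- minmax(extract_ventral_window(pert[[5]]$raw_nuclear_profile)$values)
  expect_lt(max(abs(a - b)), 0.02)
})
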