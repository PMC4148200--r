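# Reaction-transport dynamics on the compartment ring.
#
# Per compartment j with centre angle theta_j:
#   binding flux     B_j = k_b * d_j * c_j - k_D(theta_j) * dc_j
#   shuttling flux   N_j = k_i * A_nuc * d_j - k_e * A_nuc * dn_j   (amount/min)
#   d'_j  = -B_j - N_j/V_cyt + Gamma * (d_{j-1} - 2 d_j + d_{j+1})
#   c'_j  = -B_j + P_Cact - k_Deg * c_j + Gamma * Laplacian(c)_j
#   dc'_j =  B_j + Gamma * Laplacian(dc)_j
#   dn'_j =  N_j / V_nuc
# with periodic indices. Dl is neither produced nor degraded, so the
# volume-weighted total of d + dc + dn is a conserved quantity; free Cact is
# produced at P_Cact and degraded at k_Deg (the complex is protected).

#' Model right-hand side (reference implementation)
#'
#' Time derivative of the compartment state under the reaction-transport
#' model. This is the plain-R reference; the integrators use an equivalent
#' compiled version (see [simulate_final_cycle()]), and equality of the two
#' is part of the test suite.
#'
#' @param state List with numeric vectors `d`, `c`, `dc` (cytoplasmic free
#'   Dl, free Cact, Dl-Cact complex) and `dn` (nuclear Dl), each of length
#'   `geom$n_compartments`.
#' @param time Time (minutes); the system is autonomous, included for solver
#'   compatibility.
#' @param params A `dl_params` object.
#' @param geom A `dl_geometry` from [build_geometry()].
#' @return List of derivative vectors `d`, `c`, `dc`, `dn`.
#' @export
dl_rhs <- function(state, time, params, geom) {
  n <- geom$n_compartments
  stopifnot(length(state$d) == n, length(state$c) == n,
            length(state$dc) == n, length(state$dn) == n)
  vals <- c(state$d, state$c, state$dc, state$dn)
  if (any(!is.finite(vals))) {
    bad <- ((which(!is.finite(vals))[1] - 1) %% n) + 1
    stop("non-finite state at compartment ", bad, call. = FALSE)
  }
  kD <- toll_dissociation_rate(geom$theta, params$R, params$S, params$xi)
  im <- c(n, seq_len(n - 1L))
  ip <- c(seq_len(n)[-1L], 1L)
  lap <- function(x) x[im] - 2 * x + x[ip]
  B <- params$k_b * state$d * state$c - kD * state$dc
  N <- params$k_i * geom$A_nuc * state$d - params$k_e * geom$A_nuc * state$dn
  list(
    d = -B - N / geom$V_cyt + params$Gamma * lap(state$d),
    c = -B + params$P_Cact - params$k_Deg * state$c +
      params$Gamma * lap(state$c),
    dc = B + params$Gamma * lap(state$dc),
    dn = N / geom$V_nuc
  )
}

# Parameter vector consumed by the compiled rhs/Jacobian.
pack_parms <- function(params, geom) {
  kD <- toll_dissociation_rate(geom$theta, params$R, params$S, params$xi)
  c(geom$n_compartments, params$Gamma, params$k_i, params$k_e, params$P_Cact,
    params$k_Deg, params$k_b, geom$A_nuc, geom$V_nuc, geom$V_cyt, kD)
}

# Persistent negative concentrations indicate integration failure; tiny
# undershoot is a solver artifact and is clipped.
clip_negatives <- function(y, tol = 1e-9) {
  low <- min(y)
  if (low < -tol)
    stop("integration produced negative concentrations (min = ", low, ")",
         call. = FALSE)
  pmax(y, 0)
}

#' Simulate one final-cycle interphase
#'
#' Integrates the reaction-transport equations over the final nuclear cycle,
#' starting from spatially uniform cytoplasmic concentrations
#' (`Dl0`, `Cact0`, `DlCact0`) and empty nuclei (`dn = 0`, as nuclear
#' envelopes re-form after mitosis), from time 0 to `params$t` minutes.
#'
#' @param params A `dl_params` object.
#' @param times Optional vector of intermediate output times (minutes); the
#'   final state is always computed at `params$t`.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param method deSolve integration method (default `"lsoda"`,
#'   stiff-capable).
#' @param compiled Use the compiled rhs and analytic Jacobian (default);
#'   `FALSE` falls back to the plain-R [dl_rhs()].
#' @return A `dl_sim` object: `final_state` (list `d`, `c`, `dc`, `dn`),
#'   `raw_nuclear_profile` (= `dn`), `geometry`, `params`, optional
#'   `trajectory` (deSolve matrix at `times`), and `diagnostics` (relative
#'   total-Dl drift, solver step/evaluation counts).
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_final_cycle(load_parameter_set("mel_adjusted"))
#' max(sim$raw_nuclear_profile)
#' }
simulate_final_cycle <- function(params, times = NULL, rtol = 1e-8,
                                 atol = 1e-10, method = "lsoda",
                                 compiled = TRUE) {
  stopifnot(inherits(params, "dl_params"))
  geom <- build_geometry(params)
  n <- geom$n_compartments
  y0 <- c(rep(params$Dl0, n), rep(params$Cact0, n), rep(params$DlCact0, n),
          rep(0, n))
  out_times <- sort(unique(c(0, times, params$t)))

  if (compiled) {
    parms <- pack_parms(params, geom)
    f <- function(t, y, p) list(.Call(dl_rhs_c, y, p))
    jac <- function(t, y, p) .Call(dl_jac_c, y, p)
    sol <- deSolve::ode(y0, out_times, f, parms, method = method,
                        rtol = rtol, atol = atol,
                        jacfunc = jac, jactype = "fullusr")
  } else {
    f <- function(t, y, p) {
      st <- split_state(y, n)
      dv <- dl_rhs(st, t, params, geom)
      list(c(dv$d, dv$c, dv$dc, dv$dn))
    }
    sol <- deSolve::ode(y0, out_times, f, NULL, method = method,
                        rtol = rtol, atol = atol)
  }
  diag_int <- attr(sol, "istate")
  if (diag_int[1] < 0)
    stop("solver failed (istate = ", diag_int[1], ")", call. = FALSE)
  yT <- clip_negatives(as.numeric(sol[nrow(sol), -1]))
  final_state <- split_state(yT, n)
  drift <- (total_dl(final_state, geom) -
              total_dl(split_state(y0, n), geom)) /
    total_dl(split_state(y0, n), geom)
  structure(list(
    params = params,
    geometry = geom,
    final_state = final_state,
    raw_nuclear_profile = final_state$dn,
    trajectory = if (!is.null(times)) sol,
    diagnostics = list(total_dl_drift = drift,
                       n_steps = diag_int[2], n_evals = diag_int[3])
  ), class = "dl_sim")
}

split_state <- function(y, n) {
  list(d = y[seq_len(n)], c = y[n + seq_len(n)], dc = y[2 * n + seq_len(n)],
       dn = y[3 * n + seq_len(n)])
}

#' @export
print.dl_sim <- function(x, ...) {
  cat("<dl_sim> ", x$geometry$n_compartments, " compartments, peak nuclear",
      " Dl = ", signif(max(x$raw_nuclear_profile), 6),
      ", total-Dl drift = ", signif(x$diagnostics$total_dl_drift, 3),
      "\n", sep = "")
  invisible(x)
}

#' Volume-weighted total Dorsal amount
#'
#' `sum((d + dc) * V_cyt + dn * V_nuc)` over all compartments. Dl is neither
#' produced nor degraded by the model, so this amount is conserved along any
#' trajectory and across division events.
#'
#' @param state List with vectors `d`, `c`, `dc`, `dn`.
#' @param geom A `dl_geometry`.
#' @return Total Dl amount (concentration model units × µm³).
#' @export
total_dl <- function(state, geom) {
  sum((state$d + state$dc) * geom$V_cyt) + sum(state$dn * geom$V_nuc)
}

#' Effective diffusion coefficient of the compartment-hopping transport
#'
#' Converts the inter-compartment transport rate constant into a diffusion
#' coefficient via the compartment arc width at mid-cortex:
#' `D = Gamma * w_arc^2` (µm²/min).
#'
#' @param Gamma Transport rate constant (per minute).
#' @param geom A `dl_geometry`.
#' @return Diffusion coefficient (µm²/min).
#' @export
#' @examples
#' g <- build_geometry(load_parameter_set("mel_adjusted"))
#' effective_diffusion_coefficient(2, g)
effective_diffusion_coefficient <- function(Gamma, geom) {
  stopifnot(Gamma >= 0)
  Gamma * geom$w_arc^2
}

# Default interphase durations (minutes) for the early cleavage cycles;
# the final cycle takes its duration from the parameter set.
DEFAULT_INTERPHASE <- c("10" = 9, "11" = 10, "12" = 12, "13" = 16, "14" = 21)

#' Simulate several nuclear cycles with division events
#'
#' Runs the model from `start_cycle` to the final cycle. Each cycle is
#' integrated over its interphase on a ring whose nucleus count follows
#' [nuclei_at_cycle()] (total nuclei double per cycle; ring count grows by
#' sqrt(2)) and whose nuclear radius follows the piecewise-linear `profile`
#' (see [default_radius_profile()]). At each mitosis, nuclear Dl returns to
#' the cytoplasm of the parent compartment and all cytoplasmic amounts are
#' redistributed onto the finer ring by conservative overlap weighting, so
#' total Dl is carried across divisions exactly.
#'
#' Within a cycle the nuclear pool is integrated as an amount
#' (`m = dn * V_nuc`), so a growing nucleus dilutes its contents without
#' creating or destroying Dl.
#'
#' @param params A `dl_params` object; `params$n`, `params$r`, `params$t`
#'   describe the final cycle.
#' @param start_cycle First simulated cycle (default 10).
#' @param final_cycle Last cycle; defaults to the fixture metadata, else 14.
#' @param profile Nuclear-radius anchors per cycle (data frame with `cycle`,
#'   `r_start`, `r_end`); default [default_radius_profile()]. Pass `NULL`
#'   for a constant radius `params$r` throughout.
#' @param interphase Named vector of interphase durations per cycle
#'   (minutes); defaults to standard cleavage timings with the final cycle
#'   taken from `params$t`.
#' @param rtol,atol Solver tolerances.
#' @return List of per-cycle records, each with `cycle`, `geometry`,
#'   `final_state`, `raw_nuclear_profile`, `interphase`, `r_end`,
#'   `total_dl_start`, `total_dl_end`, and (except the last cycle)
#'   `total_dl_after_division`.
#' @export
simulate_multicycle <- function(params, start_cycle = 10, final_cycle = NULL,
                                profile = "default", interphase = NULL,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "dl_params"))
  fc <- final_cycle %||% attr(params, "meta")$final_cycle
  if (is.null(fc) || is.na(fc)) fc <- 14L
  if (identical(profile, "default"))
    profile <- default_radius_profile(params$r, start_cycle, fc)
  if (start_cycle > fc)
    stop("start_cycle must not exceed the final cycle", call. = FALSE)
  cycles <- start_cycle:fc
  if (is.null(interphase)) {
    interphase <- DEFAULT_INTERPHASE[as.character(cycles)]
    interphase[is.na(interphase)] <- 10
    names(interphase) <- cycles
    interphase[as.character(fc)] <- params$t
  }

  results <- vector("list", length(cycles))
  state_conc <- NULL
  prev_geom <- NULL
  for (i in seq_along(cycles)) {
    cyc <- cycles[i]
    n_c <- nuclei_at_cycle(params$n, cyc, fc)
    Tn_c <- max(round(params$Tn * 2^(-(fc - cyc))), n_c)
    r_end <- if (is.null(profile)) params$r
             else profile$r_end[profile$cycle == cyc]
    p_c <- set_params(params, n = n_c, Tn = Tn_c, r = r_end)
    geom <- build_geometry(p_c)
    n <- geom$n_compartments

    if (is.null(state_conc)) {
      state_conc <- list(d = rep(params$Dl0, n), c = rep(params$Cact0, n),
                         dc = rep(params$DlCact0, n))
    } else {
      # mitosis: nuclear Dl back to the parent compartment's cytoplasm, then
      # conservative redistribution of cytoplasmic amounts to the finer ring
      amt <- rbind(state_conc$d * prev_geom$V_cyt + state_conc$mn,
                   state_conc$c * prev_geom$V_cyt,
                   state_conc$dc * prev_geom$V_cyt)
      new_amt <- repartition_ring(amt, prev_geom$n_compartments, n)
      results[[i - 1]]$total_dl_after_division <-
        sum(new_amt[1, ]) + sum(new_amt[3, ])
      state_conc <- list(d = new_amt[1, ] / geom$V_cyt,
                         c = new_amt[2, ] / geom$V_cyt,
                         dc = new_amt[3, ] / geom$V_cyt)
    }

    dur <- unname(interphase[as.character(cyc)])
    sim <- integrate_cycle(p_c, geom, state_conc, dur, cyc, profile,
                           rtol, atol)
    state_conc <- sim$state      # includes nuclear amount mn
    prev_geom <- geom
    results[[i]] <- list(cycle = cyc, geometry = geom,
                         final_state = sim$final_state,
                         raw_nuclear_profile = sim$final_state$dn,
                         interphase = dur, r_end = r_end,
                         total_dl_start = sim$total_start,
                         total_dl_end = sim$total_end)
  }
  results
}

# One interphase with time-varying nuclear radius; nuclear pool in amounts.
integrate_cycle <- function(p_c, geom, state_conc, dur, cyc, profile,
                            rtol, atol) {
  n <- geom$n_compartments
  kD <- toll_dissociation_rate(geom$theta, p_c$R, p_c$S, p_c$xi)
  im <- c(n, seq_len(n - 1L)); ip <- c(seq_len(n)[-1L], 1L)
  r_of <- function(time) nuclear_radius_at(time, cyc, profile,
                                           interphase = dur,
                                           r_const = p_c$r)
  f <- function(time, y, parms) {
    d <- y[seq_len(n)]; cc <- y[n + seq_len(n)]
    dc <- y[2 * n + seq_len(n)]; mn <- y[3 * n + seq_len(n)]
    r_t <- r_of(min(time, dur))
    A_t <- 4 * pi * r_t^2
    V_t <- 4 / 3 * pi * r_t^3
    B <- p_c$k_b * d * cc - kD * dc
    N <- p_c$k_i * A_t * d - p_c$k_e * A_t * (mn / V_t)
    list(c(-B - N / geom$V_cyt + p_c$Gamma * (d[im] - 2 * d + d[ip]),
           -B + p_c$P_Cact - p_c$k_Deg * cc +
             p_c$Gamma * (cc[im] - 2 * cc + cc[ip]),
           B + p_c$Gamma * (dc[im] - 2 * dc + dc[ip]),
           N))
  }
  y0 <- c(state_conc$d, state_conc$c, state_conc$dc, rep(0, n))
  total0 <- sum((y0[seq_len(n)] + y0[2 * n + seq_len(n)]) * geom$V_cyt)
  sol <- deSolve::ode(y0, c(0, dur), f, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("solver failed in cycle ", cyc, call. = FALSE)
  yT <- clip_negatives(as.numeric(sol[nrow(sol), -1]))
  d <- yT[seq_len(n)]; cc <- yT[n + seq_len(n)]
  dc <- yT[2 * n + seq_len(n)]; mn <- yT[3 * n + seq_len(n)]
  V_end <- 4 / 3 * pi * r_of(dur)^3
  list(state = list(d = d, c = cc, dc = dc, mn = mn),
       final_state = list(d = d, c = cc, dc = dc, dn = mn / V_end),
       total_start = total0,
       total_end = sum((d + dc) * geom$V_cyt) + sum(mn))
}

# Conservative redistribution of per-compartment amounts from an n_old ring
# to an n_new ring. Row species x column compartments. Each old angular bin
# spreads its amount uniformly over its arc; new bins collect by overlap.
repartition_ring <- function(amounts, n_old, n_new) {
  W <- ring_overlap_matrix(n_old, n_new)
  amounts %*% t(W)
}

# W[k, j] = fraction of old bin j's arc covered by new bin k; columns sum to 1.
ring_overlap_matrix <- function(n_old, n_new) {
  do <- 2 * pi / n_old
  dn_ <- 2 * pi / n_new
  old_lo <- (seq_len(n_old) - 1) * do - do / 2
  new_lo <- (seq_len(n_new) - 1) * dn_ - dn_ / 2
  W <- matrix(0, n_new, n_old)
  for (k in seq_len(n_new)) {
    for (shift in c(-2 * pi, 0, 2 * pi)) {
      a <- new_lo[k] + shift
      b <- a + dn_
      ov <- pmin(b, old_lo + do) - pmax(a, old_lo)
      pos <- ov > 1e-15
      W[k, pos] <- W[k, pos] + ov[pos] / do
    }
  }
  W
}

#' Pairwise shape deviation of multicycle gradient profiles
#'
#' Peak-normalizes each cycle's nuclear profile and compares cycles pairwise
#' by maximum absolute difference, after linear interpolation onto a common
#' angular grid (cycles have different ring sizes, so nucleus indices are not
#' comparable across cycles).
#'
#' @param results Output of [simulate_multicycle()].
#' @param cycles Cycles to compare (default: all but the first).
#' @param grid_points Number of points on the common angular grid.
#' @return Data frame with columns `cycle_a`, `cycle_b`, `max_abs_diff`.
#' @export
multicycle_shape_deviation <- function(results, cycles = NULL,
                                       grid_points = 181) {
  all_cycles <- vapply(results, function(r) r$cycle, numeric(1))
  if (is.null(cycles)) cycles <- all_cycles[-1]
  keep <- results[all_cycles %in% cycles]
  grid <- seq(-pi, pi, length.out = grid_points)
  profs <- lapply(keep, function(r) {
    th <- r$geometry$theta
    o <- order(th)
    v <- r$raw_nuclear_profile / max(r$raw_nuclear_profile)
    stats::approx(th[o], v[o], xout = grid, rule = 2)$y
  })
  pairs <- utils::combn(length(profs), 2)
  data.frame(
    cycle_a = vapply(pairs[1, ], function(i) keep[[i]]$cycle, numeric(1)),
    cycle_b = vapply(pairs[2, ], function(i) keep[[i]]$cycle, numeric(1)),
    max_abs_diff = apply(pairs, 2, function(ij)
      max(abs(profs[[ij[1]]] - profs[[ij[2]]])))
  )
}
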