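# Fixed-step explicit-Euler integrator, written directly from the model
# equations (independent of dl_rhs / the compiled rhs).
euler_simulate <- function(params, dt = 1e-4, t_end = params$t) {
  geom <- build_geometry(params)
  n <- geom$n_compartments
  kD <- params$R * exp(-params$S * abs(geom$theta / pi)^params$xi)
  im <- c(n, seq_len(n - 1)); ip <- c(seq_len(n)[-1], 1)
  d <- rep(params$Dl0, n); cc <- rep(params$Cact0, n)
  dc <- rep(params$DlCact0, n); dn <- rep(0, n)
  for (s in seq_len(round(t_end / dt))) {
    B <- params$k_b * d * cc - kD * dc
    N <- params$k_i * geom$A_nuc * d - params$k_e * geom$A_nuc * dn
    d_new  <- d  + dt * (-B - N / geom$V_cyt +
                           params$Gamma * (d[im] - 2 * d + d[ip]))
    cc_new <- cc + dt * (-B + params$P_Cact - params$k_Deg * cc +
                           params$Gamma * (cc[im] - 2 * cc + cc[ip]))
    dc_new <- dc + dt * (B + params$Gamma * (dc[im] - 2 * dc + dc[ip]))
    dn_new <- dn + dt * (N / geom$V_nuc)
    d <- d_new; cc <- cc_new; dc <- dc_new; dn <- dn_new
  }
  list(d = d, c = cc, dc = dc, dn = dn)
}
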