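# Small 12-compartment instance with gentle kinetics: every rate is well
# inside the stability/accuracy regime of a fixed-step explicit Euler
# integrator at dt = 1e-4 min, so it can serve as an oracle target.
oracle_params <- function() {
  parameter_set(El = 241.5, Er = 102.4, Eh = 25, Tn = 780,
                R = 0.5, S = 4, xi = 2.5, Gamma = 0.1,
                k_i = 0.3, k_e = 0.3, P_Cact = 2, k_Deg = 0.2, k_b = 0.01,
                Dl0 = 36, DlCact0 = 30, Cact0 = 36,
                r = 3.08, n = 12, t = 2)
}

minmax <- function(v) (v - min(v)) / (max(v) - min(v))

# random non-negative compartment state
random_state <- function(n, seed) {
  set.seed(seed)
  list(d = runif(n, 0, 50), c = runif(n, 0, 50),
       dc = runif(n, 0, 50), dn = runif(n, 0, 300))
}
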