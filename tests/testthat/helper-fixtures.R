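# Shared fixtures. Everything is generated in code; the expensive
# single-cell runs used by several residence-time tests are built once per
# session.

fluct <- preset("fluctuation")
osc <- preset("oscillation")

# long fluctuation-scenario trajectory with several hundred Nanog-low
# sojourns (dt fine enough that the mean sojourn is step-converged)
fluct_long_traj <- local({
  cfg <- sim_config(dt = 2e-5, t_end = 150, record_every = 2L, seed = 101L)
  simulate_cell(fluct, cfg)
})

# oscillation-scenario trajectory covering ~12 noisy cycles
osc_long_traj <- local({
  cfg <- sim_config(dt = 2e-3, t_end = 1000, record_every = 5L, seed = 102L)
  simulate_cell(osc, cfg)
})

# forward-Euler reference integrator written independently of the compiled
# path (plain R loop), used as the sigma = 0 oracle
euler_reference <- function(p, y0, t_end, dt) {
  nst <- ceiling(t_end / dt)
  out <- matrix(NA_real_, nst + 1, 4,
                dimnames = list(NULL, c("t", "os", "n", "x")))
  os <- y0[["os"]]; n <- y0[["n"]]
  x <- if ("x" %in% names(y0)) y0[["x"]] else 0
  out[1, ] <- c(0, os, n, x)
  osc_flag <- p$scenario == "oscillation"
  for (i in seq_len(nst)) {
    h <- function(c, k, g) c^g / (k + c^g)
    prod_os <- p$u * (p$s1 / p$d_o) * (p$s2 / p$d_s) *
      h(os, p$k1, p$gamma_os) * h(os, p$k2, p$gamma_os)
    s6x <- if (osc_flag) p$s6 * x^p$gamma_x else 0
    ng <- n^p$gamma_n
    prod_n <- p$s3 * h(os, p$k3, p$gamma_os) + p$s4 * ng / (p$k4 + ng + s6x)
    dx <- if (osc_flag) p$s5 * h(n, p$k5, p$gamma_n) - p$d_x * x else 0
    os <- os + (prod_os - p$d_os * os) * dt
    n <- n + (prod_n - p$d_n * n) * dt
    if (osc_flag) x <- x + dx * dt
    if (n < 0) n <- 0
    out[i + 1, ] <- c(i * dt, os, n, x)
  }
  out
}
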