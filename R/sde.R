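# Euler-Maruyama simulation of single cells and independent-cell ensembles.
# The deterministic drift advances all species; the Gaussian white-noise term
# sigma*sqrt(dt)*eta is added to the Nanog component only, and [N] is clamped
# at zero after every step. The inner loop is compiled (src/em.cpp) and draws
# its normal variates from R's RNG, so results are reproducible from a seed.

#' Simulation configuration
#'
#' @param dt integration step (time units).
#' @param t_end duration of the simulation.
#' @param record_every record every k-th step (thinning; 1 keeps every step).
#' @param seed integer master seed; every source of randomness in a run is
#'   derived from it.
#' @param n_cells ensemble size for [simulate_population()].
#' @param init optional initial state, a named vector with `os`, `n`
#'   (and `x`); `NULL` selects the scenario default (see
#'   [simulate_population()]).
#' @param clamp_all clamp `[OS]` and `[X]` at zero in addition to `[N]`
#'   (inert under the default dynamics since only Nanog receives noise).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-4, t_end = 10, record_every = 1L, seed = 1L,
                       n_cells = 1L, init = NULL, clamp_all = TRUE) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (t_end < dt) stop("t_end must be >= dt", call. = FALSE)
  if (record_every < 1) stop("record_every must be >= 1", call. = FALSE)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  structure(list(dt = dt, t_end = t_end,
                 record_every = as.integer(record_every),
                 seed = as.integer(seed), n_cells = as.integer(n_cells),
                 init = init, clamp_all = isTRUE(clamp_all)),
            class = "sim_config")
}

# Deterministic per-cell seed derivation from the master seed (Lehmer-style
# mixing, kept below 2^31).
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + i * 16807) %%
               2147483647)
}

default_init <- function(p) {
  osv <- os_operating_point(p)
  if (p$scenario == "oscillation") {
    y <- cycle_samples(p)[1, ]
    c(os = osv, n = y[1], x = y[2])
  } else {
    fps <- nanog_fixed_points(p, osv)
    hi <- max(fps[fps$stability == "STABLE", "n"])
    c(os = osv, n = hi, x = 0)
  }
}

#' Simulate a single cell
#'
#' Integrates one stochastic trajectory of the scenario's dynamics with the
#' Euler-Maruyama scheme: deterministic step `dt` for every species plus a
#' `sigma*sqrt(dt)`-scaled standard-normal increment on the Nanog component,
#' followed by the non-negativity clamp. With `sigma = 0` the scheme reduces
#' exactly to forward Euler on the ODE system.
#'
#' @param p a `scenario_params` object.
#' @param cfg a [sim_config()].
#' @param sig optional [signal_params()] applying the gated differentiation
#'   signal during its window.
#' @param sigma noise amplitude; defaults to `p$sigma`.
#' @return A `trajectory`: a data frame with columns `t`, `os`, `n`, `x` and
#'   attributes `params`, `config`, `seed`.
#' @export
simulate_cell <- function(p, cfg, sig = NULL, sigma = p$sigma) {
  stopifnot(inherits(p, "scenario_params"), inherits(cfg, "sim_config"))
  init <- cfg$init %||% default_init(p)
  y0 <- c(init[["os"]], init[["n"]],
          if ("x" %in% names(init)) init[["x"]] else 0)
  set.seed(cfg$seed)
  m <- .em_simulate(y0, 0, cfg$t_end, cfg$dt, cfg$record_every,
                    pack_params(p, sig), sigma, cfg$clamp_all, FALSE)
  tr <- as.data.frame(m)
  attr(tr, "params") <- p
  attr(tr, "config") <- cfg
  attr(tr, "seed") <- cfg$seed
  class(tr) <- c("trajectory", "data.frame")
  tr
}

#' Simulate an ensemble of independent cells
#'
#' Each cell is an independent realization of the stochastic model, run with
#' its own seed derived deterministically from the master seed (so
#' `n_cells = 1` reproduces [simulate_cell()] under the derived seed).
#' Default initial conditions follow the scenario: fluctuation-scenario
#' cells start at the Nanog-high fixed point and are equilibrated by the
#' burn-in; oscillation-scenario cells start at uniformly random phases of
#' the deterministic limit cycle, so the ensemble is spread over the cycle
#' from the outset.
#'
#' @param p a `scenario_params` object.
#' @param cfg a [sim_config()] with `n_cells` set.
#' @param sig optional [signal_params()].
#' @param snapshot_only keep only the final state of each cell (memory-light
#'   population snapshots).
#' @return An `ensemble` object: a list with `snapshot` (data frame of final
#'   states per cell) and, unless `snapshot_only`, `trajectories` (list of
#'   `trajectory` objects).
#' @export
simulate_population <- function(p, cfg, sig = NULL, snapshot_only = TRUE) {
  stopifnot(inherits(p, "scenario_params"), inherits(cfg, "sim_config"))
  inits <- population_inits(p, cfg)
  par <- pack_params(p, sig)
  snap <- matrix(NA_real_, cfg$n_cells, 4,
                 dimnames = list(NULL, c("t", "os", "n", "x")))
  trajs <- if (snapshot_only) NULL else vector("list", cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    set.seed(derive_seed(cfg$seed, i))
    m <- .em_simulate(inits[i, ], 0, cfg$t_end, cfg$dt, cfg$record_every,
                      par, p$sigma, cfg$clamp_all, snapshot_only)
    snap[i, ] <- m[nrow(m), ]
    if (!snapshot_only) {
      tr <- as.data.frame(m)
      attr(tr, "seed") <- derive_seed(cfg$seed, i)
      class(tr) <- c("trajectory", "data.frame")
      trajs[[i]] <- tr
    }
  }
  snap <- as.data.frame(snap)
  snap$cell_id <- seq_len(cfg$n_cells)
  structure(list(snapshot = snap, trajectories = trajs,
                 params = p, config = cfg),
            class = "ensemble")
}

# Initial-state matrix (os, n, x) for an ensemble.
population_inits <- function(p, cfg) {
  if (!is.null(cfg$init)) {
    init <- cfg$init
    if (is.matrix(init)) return(init)
    return(matrix(c(init[["os"]], init[["n"]],
                    if ("x" %in% names(init)) init[["x"]] else 0),
                  cfg$n_cells, 3, byrow = TRUE))
  }
  if (p$scenario == "oscillation") {
    osv <- os_operating_point(p)
    cyc <- cycle_samples(p)
    set.seed(derive_seed(cfg$seed, 0L))
    idx <- sample.int(nrow(cyc), cfg$n_cells, replace = TRUE)
    cbind(osv, cyc[idx, 1], cyc[idx, 2])
  } else {
    init <- default_init(p)
    matrix(init, cfg$n_cells, 3, byrow = TRUE)
  }
}

# States sampled uniformly in time along one deterministic oscillation
# period (phase-randomization pool).
cycle_samples <- function(p, n_per_period = 2000) {
  key <- paste0("pool", n_per_period, ":", params_key(p))
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  lc <- find_limit_cycle(p)
  if (!lc$found)
    stop("no limit cycle: cannot phase-randomize the ensemble", call. = FALSE)
  osv <- os_operating_point(p)
  basal <- p$s3 * hill(osv, p$k3, p$gamma_os)
  rhs <- function(t, y, parms) {
    n <- max(y[1], 0); x <- max(y[2], 0)
    ng <- n^p$gamma_n
    list(c(basal + p$s4 * ng / (p$k4 + ng + p$s6 * x^p$gamma_x) - p$d_n * n,
           p$s5 * hill(n, p$k5, p$gamma_n) - p$d_x * x))
  }
  # converge to the cycle, then sample one period densely
  burn <- deSolve::ode(c(n = 1, x = 1), c(0, 20 * lc$period), rhs, NULL)
  y1 <- burn[nrow(burn), 2:3]
  times <- seq(0, lc$period, length.out = n_per_period + 1)[-1]
  sol <- deSolve::ode(c(n = y1[[1]], x = y1[[2]]), c(0, times), rhs, NULL)
  cache_set(key, unname(sol[-1, 2:3, drop = FALSE]))
}

#' Step-halving convergence report for the deterministic integrator
#'
#' Runs the `sigma = 0` system at `dt`, `dt/2` and a fine reference step
#' (`dt/100`), and reports the global error of the final state against the
#' reference together with the observed convergence order
#' `log2(err(dt) / err(dt/2))`, which is ~1 for forward Euler.
#'
#' @param p a `scenario_params` object.
#' @param cfg a [sim_config()]; its `dt` is the coarse step.
#' @return A list with `err_dt`, `err_half`, `observed_order`.
#' @export
convergence_check <- function(p, cfg) {
  run <- function(dt) {
    c2 <- cfg; c2$dt <- dt; c2$record_every <- 1L
    tr <- simulate_cell(p, c2, sigma = 0)
    unlist(tr[nrow(tr), c("os", "n", "x")])
  }
  ref <- run(cfg$dt / 100)
  e1 <- max(abs(run(cfg$dt) - ref))
  e2 <- max(abs(run(cfg$dt / 2) - ref))
  list(err_dt = e1, err_half = e2, observed_order = log2(e1 / e2))
}

#' Write a trajectory or ensemble snapshot to CSV
#'
#' Trajectories are written with columns `t, os, n, x, cell_id`; snapshots
#' with `os, n, x, cell_id`.
#'
#' @param x a `trajectory` or `ensemble` object.
#' @param path output file path.
#' @param cell_id id recorded for a single trajectory.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path, cell_id = 1L) {
  if (inherits(x, "trajectory")) {
    df <- as.data.frame(x)
    df$cell_id <- cell_id
  } else if (inherits(x, "ensemble")) {
    df <- x$snapshot
  } else stop("x must be a trajectory or ensemble", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
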