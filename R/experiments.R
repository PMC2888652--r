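# In-silico experiments: sorting a stationary population into Nanog-low /
# Nanog-high subpopulations and following the re-establishment of the
# bimodal distribution, and challenging single cells with a gated
# differentiation signal. These are the protocols that discriminate the two
# heterogeneity mechanisms experimentally.

#' Sort-and-re-establish experiment
#'
#' Simulates a stationary population, sorts the cells at the snapshot cut
#' into a Nanog-low or Nanog-high subpopulation, and follows the Nanog-low
#' fraction of the sorted subpopulation over time until the bimodal
#' equilibrium re-establishes. Under noise-driven switching the fraction
#' relaxes aperiodically; under the oscillation mechanism sorting
#' synchronizes the cells on the limit cycle, so the fraction shows damped
#' oscillations and transiently overshoots its equilibrium ("over-shooting",
#' strongest when Nanog-low cells are selected).
#'
#' The overshoot predicate compares the early transient of the
#' opposing-state fraction with the series' own late plateau (the last
#' quarter of the recorded time points): an overshoot is declared when at
#' least three consecutive early points exceed the plateau mean by more
#' than `se_factor` binomial standard errors of the followed subpopulation.
#' Referencing the plateau absorbs the Monte-Carlo error of the pre-sort
#' equilibrium estimate; the persistence requirement suppresses single-point
#' noise excursions, while the synchronized sweep of an oscillating cohort
#' holds the opposing fraction near 100% for a sustained stretch.
#'
#' @param p a `scenario_params` object.
#' @param cfg a [sim_config()]; `t_end` is the burn-in used to reach
#'   stationarity before sorting, `n_cells` the pre-sort population size.
#' @param sorted_state `"LOW"` or `"HIGH"`: which subpopulation is kept.
#' @param t_follow duration over which the sorted subpopulation is followed.
#' @param n_record number of time points of the fraction series.
#' @param cut snapshot classification cut; defaults to the unstable Nanog
#'   fixed point.
#' @param se_factor multiple of the binomial standard error defining the
#'   overshoot band (combined with the three-point persistence rule).
#' @return An object of class `sort_experiment`: list with `scenario`,
#'   `sorted_state`, `times`, `fraction_low`, `equilibrium_fraction`,
#'   `n_sorted`, `overshoot` (logical) and `overshoot_magnitude`.
#' @export
run_sort_and_reestablish <- function(p, cfg, sorted_state = c("LOW", "HIGH"),
                                     t_follow = NULL, n_record = 80,
                                     cut = NULL, se_factor = 2.5) {
  sorted_state <- match.arg(sorted_state)
  if (is.null(cut)) cut <- nanog_separatrix(p)
  ens <- simulate_population(p, cfg)
  snap <- ens$snapshot
  eq_frac <- mean(snap$n < cut)
  keep <- if (sorted_state == "LOW") snap$n < cut else snap$n >= cut
  if (!any(keep))
    stop("sorted ", sorted_state, " subpopulation is empty", call. = FALSE)
  states <- as.matrix(snap[keep, c("os", "n", "x")])
  n_sorted <- nrow(states)
  if (is.null(t_follow)) {
    t_follow <- if (p$scenario == "oscillation") {
      lc <- find_limit_cycle(p)
      if (lc$found) 4 * lc$period else 4
    } else 2
  }
  times <- seq(0, t_follow, length.out = n_record + 1)
  frac <- numeric(length(times))
  frac[1] <- fraction_low(states[, "n"], cut)
  set.seed(derive_seed(cfg$seed, 999983L))
  par <- pack_params(p)
  for (i in seq_len(n_record)) {
    states <- .em_evolve_ensemble(states, times[i], times[i + 1], cfg$dt,
                                  par, p$sigma, cfg$clamp_all)
    frac[i + 1] <- fraction_low(states[, "n"], cut)
  }
  # overshoot: sustained early exceedance of the opposing-state fraction
  # over the series' own late plateau
  if (n_sorted > 1 && n_record >= 8) {
    opp <- if (sorted_state == "LOW") 1 - frac[-1] else frac[-1]
    k <- max(5L, length(opp) %/% 4L)
    base <- mean(utils::tail(opp, k))
    se <- sqrt(max(base * (1 - base), 0.25 / n_sorted) / n_sorted)
    early <- utils::head(opp, length(opp) - k)
    above <- early > base + se_factor * se
    runs <- rle(above)
    overshoot <- any(runs$values & runs$lengths >= 3L)
    overshoot_mag <- max(c(early - base, 0))
  } else {
    overshoot <- NA
    overshoot_mag <- NA_real_
  }
  structure(list(scenario = p$scenario, sorted_state = sorted_state,
                 times = times, fraction_low = frac,
                 equilibrium_fraction = eq_frac, n_sorted = n_sorted,
                 overshoot = overshoot, overshoot_magnitude = overshoot_mag),
            class = "sort_experiment")
}

#' @export
print.sort_experiment <- function(x, ...) {
  cat(sprintf(
    "sort experiment (%s, sorted %s, %d cells): equilibrium fraction %.3f, %s\n",
    x$scenario, x$sorted_state, x$n_sorted, x$equilibrium_fraction,
    if (isTRUE(x$overshoot))
      sprintf("overshoot by %.3f", x$overshoot_magnitude)
    else "no overshoot"))
  invisible(x)
}

#' Differentiation-challenge experiment
#'
#' Simulates a single cell, waits for its first entry into the trigger
#' state (Nanog-low or Nanog-high), applies the gated differentiation
#' signal Y for a fixed window starting there, and reports whether the
#' Oct4-Sox2 level collapses (DIFFERENTIATED: final `[OS]` below the
#' unstable OS fixed point, from which the heterodimer auto-regulation
#' cannot recover) or returns to its high fixed point (MAINTAINED). Because
#' high Nanog blocks the signal, only a window hitting a Nanog-low cell can
#' collapse the network - and once `[OS]` has collapsed, the basal Nanog
#' activation is gone and the Nanog-low state becomes permanent (no further
#' LOW/HIGH transitions).
#'
#' @param p a `scenario_params` object.
#' @param cfg a [sim_config()]; `t_end` limits the wait for the trigger
#'   state plus the follow-up.
#' @param sig a [signal_params()]; its window length `t_off - t_on` is kept,
#'   the onset is moved to the first entry into the trigger state (unless
#'   `at_first_entry = FALSE`, which applies the window as given).
#' @param trigger `"LOW"` or `"HIGH"`.
#' @param at_first_entry logical, see above.
#' @param t_follow time simulated after the signal window.
#' @return An object of class `challenge_result`: list with `scenario`,
#'   `signal` (the placed window), `trigger`, `outcome`
#'   (`"MAINTAINED"`/`"DIFFERENTIATED"`), `final_os`, `os_unstable`,
#'   `trajectory`, `post_signal_transitions`.
#' @export
run_differentiation_challenge <- function(p, cfg, sig,
                                          trigger = c("LOW", "HIGH"),
                                          at_first_entry = TRUE,
                                          t_follow = 5) {
  trigger <- match.arg(trigger)
  stopifnot(inherits(sig, "signal_params"))
  th <- default_thresholds(p)
  window <- sig$t_off - sig$t_on
  if (at_first_entry) {
    scout <- simulate_cell(p, cfg)
    # the signal must hit a cell RESIDING in the trigger state, so the
    # window is placed at the first crossing into the state's core region
    # (log-midpoint between the separatrix and the state's representative
    # level) rather than at the mere classification threshold, where the
    # Nanog level characterizes neither state
    n_u <- nanog_separatrix(p)
    if (p$scenario == "oscillation") {
      lc <- find_limit_cycle(p)
      n_lo <- max(lc$n_min, 1e-3); n_hi <- lc$n_max
    } else {
      fps <- nanog_fixed_points(p)
      st <- fps[fps$stability == "STABLE", "n"]
      n_lo <- max(min(st), 1e-3); n_hi <- max(st)
    }
    core <- if (trigger == "LOW") sqrt(n_lo * n_u) else sqrt(n_hi * n_u)
    nn <- scout$n
    crossed <- if (trigger == "LOW") nn[-1] <= core & nn[-length(nn)] > core
               else nn[-1] >= core & nn[-length(nn)] < core
    idx <- which(crossed)
    if (length(idx) == 0)
      stop("trigger state ", trigger, " never reached within t_end = ",
           cfg$t_end, call. = FALSE)
    t_on <- scout$t[idx[1] + 1]
    sig <- signal_params(t_on, t_on + window, sig$amplitude, sig$k_gate,
                         sig$gamma_gate)
  }
  cfg2 <- cfg
  cfg2$t_end <- sig$t_off + t_follow
  tr <- simulate_cell(p, cfg2, sig = sig)
  os_fps <- os_fixed_points(p)
  os_un <- os_fps[os_fps$stability == "UNSTABLE", "os"]
  os_un <- if (length(os_un)) max(os_un) else 0
  final_os <- tr$os[nrow(tr)]
  outcome <- if (final_os < os_un) "DIFFERENTIATED" else "MAINTAINED"
  post <- tr[tr$t >= sig$t_off, , drop = FALSE]
  post_trans <- if (nrow(post) >= 2) {
    pr <- classify_states(post, th, f = p$f)
    nrow(pr) - 1L
  } else 0L
  structure(list(scenario = p$scenario, signal = sig, trigger = trigger,
                 outcome = outcome, final_os = final_os,
                 os_unstable = os_un, trajectory = tr,
                 post_signal_transitions = post_trans),
            class = "challenge_result")
}

#' @export
print.challenge_result <- function(x, ...) {
  cat(sprintf(
    "differentiation challenge (%s, trigger %s, window [%.3g, %.3g)): %s (final [OS] %.3g)\n",
    x$scenario, x$trigger, x$signal$t_on, x$signal$t_off, x$outcome,
    x$final_os))
  invisible(x)
}

#' Reproduce a figure-level analysis bundle
#'
#' End-to-end drivers writing the data behind each figure-level analysis as
#' CSV/JSON files into `out_dir`: `fig2` - fluctuation-scenario bifurcation
#' diagram in s4, a typical single-cell trajectory, and the stationary
#' population histogram; `fig3` - the oscillation-scenario analogues in s6
#' plus the Nanog-vs-X phase portrait with and without noise; `fig4` - the
#' four sort-and-re-establish experiments; `fig5` - residence-time
#' distributions for both scenarios; `fig6` - the four differentiation
#' challenges. Deterministic given the master seed; re-running overwrites
#' the same files with identical content.
#'
#' @param figure_id one of `"fig2"`, `"fig3"`, `"fig4"`, `"fig5"`, `"fig6"`.
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param scale factor in (0, 1] shrinking ensemble sizes and run lengths
#'   for quick desk runs.
#' @return Invisibly, a character vector of the files written.
#' @export
reproduce <- function(figure_id, out_dir = ".", seed = 1L, scale = 1) {
  if (!figure_id %in% paste0("fig", 2:6))
    stop("unknown figure id '", figure_id, "'; valid: fig2..fig6",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- switch(figure_id,
    fig2 = reproduce_fig2(out_dir, seed, scale),
    fig3 = reproduce_fig3(out_dir, seed, scale),
    fig4 = reproduce_fig4(out_dir, seed, scale),
    fig5 = reproduce_fig5(out_dir, seed, scale),
    fig6 = reproduce_fig6(out_dir, seed, scale))
  invisible(files)
}

res_file <- function(out_dir, name) file.path(out_dir, name)

reproduce_fig2 <- function(out_dir, seed, scale) {
  p <- preset("fluctuation")
  b <- scan_bifurcation(p, "s4", seq(0, 30, by = 0.25))
  f1 <- res_file(out_dir, "fig2_bifurcation_s4.csv")
  write_bifurcation_csv(b, f1)
  cfg <- sim_config(dt = 1e-4, t_end = max(2, 20 * scale),
                    record_every = 10L, seed = seed)
  tr <- simulate_cell(p, cfg)
  f2 <- res_file(out_dir, "fig2_trajectory.csv")
  write_trajectory_csv(tr, f2)
  ncells <- max(100L, as.integer(5000 * scale))
  ens <- simulate_population(p, sim_config(dt = 1e-4, t_end = 10,
                                           seed = seed, n_cells = ncells))
  f3 <- res_file(out_dir, "fig2_snapshot.csv")
  write_trajectory_csv(ens, f3)
  ph <- population_histogram(ens)
  f4 <- res_file(out_dir, "fig2_density.csv")
  utils::write.csv(ph$density, f4, row.names = FALSE)
  c(f1, f2, f3, f4)
}

reproduce_fig3 <- function(out_dir, seed, scale) {
  p <- preset("oscillation")
  b <- scan_bifurcation(p, "s6", seq(0.25, 10, by = 0.25),
                        cycles = scale >= 1)
  f1 <- res_file(out_dir, "fig3_bifurcation_s6.csv")
  write_bifurcation_csv(b, f1)
  lc <- find_limit_cycle(p)
  tspan <- if (lc$found) 4 * lc$period else 200
  cfg <- sim_config(dt = 2e-3, t_end = tspan, record_every = 10L,
                    seed = seed)
  tr_noise <- simulate_cell(p, cfg)
  tr_det <- simulate_cell(p, cfg, sigma = 0)
  f2 <- res_file(out_dir, "fig3_trajectory.csv")
  write_trajectory_csv(tr_noise, f2)
  f3 <- res_file(out_dir, "fig3_phase_portrait.csv")
  utils::write.csv(data.frame(t = tr_det$t, n_det = tr_det$n,
                              x_det = tr_det$x, n_noise = tr_noise$n,
                              x_noise = tr_noise$x),
                   f3, row.names = FALSE)
  ncells <- max(100L, as.integer(10000 * scale))
  ens <- simulate_population(p, sim_config(dt = 2e-3,
                                           t_end = max(20, 200 * scale),
                                           seed = seed, n_cells = ncells))
  f4 <- res_file(out_dir, "fig3_snapshot.csv")
  write_trajectory_csv(ens, f4)
  c(f1, f2, f3, f4)
}

reproduce_fig4 <- function(out_dir, seed, scale) {
  files <- character(0)
  for (scen in c("fluctuation", "oscillation")) {
    p <- preset(scen)
    dt <- if (scen == "oscillation") 2e-3 else 1e-4
    ncells <- max(100L, as.integer(10000 * scale))
    burn <- if (scen == "oscillation") max(20, 200 * scale) else 10
    cfg <- sim_config(dt = dt, t_end = burn, seed = seed, n_cells = ncells)
    for (ss in c("LOW", "HIGH")) {
      r <- run_sort_and_reestablish(p, cfg, ss)
      f <- res_file(out_dir, sprintf("fig4_sort_%s_%s.csv", scen,
                                     tolower(ss)))
      utils::write.csv(data.frame(t = r$times, fraction_low = r$fraction_low,
                                  equilibrium = r$equilibrium_fraction),
                       f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  files
}

reproduce_fig5 <- function(out_dir, seed, scale) {
  files <- character(0)
  for (scen in c("fluctuation", "oscillation")) {
    p <- preset(scen)
    dt <- if (scen == "oscillation") 2e-3 else 2e-5
    tend <- if (scen == "oscillation") max(500, 30000 * scale)
            else max(10, 120 * scale)
    cfg <- sim_config(dt = dt, t_end = tend, seed = seed)
    tr <- simulate_cell(p, cfg)
    rec <- classify_states(tr)
    f <- res_file(out_dir, sprintf("fig5_residence_%s.csv", scen))
    write_residence_csv(rec, f)
    files <- c(files, f)
  }
  files
}

reproduce_fig6 <- function(out_dir, seed, scale) {
  files <- character(0)
  for (scen in c("fluctuation", "oscillation")) {
    p <- preset(scen)
    dt <- if (scen == "oscillation") 2e-3 else 1e-4
    tend <- if (scen == "oscillation") 400 else 20
    cfg <- sim_config(dt = dt, t_end = tend, record_every = 10L, seed = seed)
    sig <- default_signal(p)
    for (tg in c("LOW", "HIGH")) {
      r <- run_differentiation_challenge(p, cfg, sig, tg)
      f <- res_file(out_dir, sprintf("fig6_challenge_%s_%s.csv", scen,
                                     tolower(tg)))
      write_trajectory_csv(r$trajectory, f)
      files <- c(files, f)
      summ <- res_file(out_dir, sprintf("fig6_challenge_%s_%s.json", scen,
                                        tolower(tg)))
      writeLines(sprintf(
        paste0('{"scenario":"%s","trigger":"%s","outcome":"%s",',
               '"final_os":%.6g,"post_signal_transitions":%d}'),
        scen, tg, r$outcome, r$final_os, r$post_signal_transitions), summ)
      files <- c(files, summ)
    }
  }
  files
}

#' Default differentiation-signal parameterization
#'
#' Builds a [signal_params()] object whose window length, gate placement and
#' amplitude are derived from the scenario's own dynamics:
#'
#' * the window spans one expected Nanog-low residence (fluctuation: the
#'   paper-calibrated mean `1/f`; oscillation: the deterministic low dwell of
#'   the limit cycle), so that the signal probes the state the cell is in
#'   rather than averaging over many switches;
#' * the gate half-blocks at the geometric mean of the Nanog-low and
#'   Nanog-high levels, with a steep coefficient (`gamma_gate = 6`) so that a
#'   Nanog-high cell leaks almost no signal;
#' * the amplitude is the smallest value on a logarithmic grid that drives
#'   `[OS]` from its high fixed point to below its unstable fixed point
#'   within half a window when fully un-opposed (a short calibration sweep,
#'   integrated with the un-gated removal-enhanced OS equation). The result
#'   is cached per parameter set.
#'
#' @param p a `scenario_params` object.
#' @param window signal duration (time units); `NULL` derives it as above.
#' @param gamma_gate gating Hill coefficient.
#' @return A [signal_params()] object starting at `t_on = 0` (drivers move
#'   the window to the trigger time).
#' @export
default_signal <- function(p, window = NULL, gamma_gate = 6) {
  key <- paste0("sig", format(window), ":", gamma_gate, ":", params_key(p))
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  if (p$scenario == "oscillation") {
    lc <- find_limit_cycle(p)
    if (!lc$found) stop("no limit cycle; supply an explicit window",
                        call. = FALSE)
    th <- default_thresholds(p)
    pool <- cycle_samples(p)
    t_low <- lc$period * mean(pool[, 1] < th$high_exit)
    hi <- lc$n_max; lo <- max(lc$n_min, 1e-3)
  } else {
    fps <- nanog_fixed_points(p)
    st <- fps[fps$stability == "STABLE", "n"]
    hi <- max(st); lo <- min(st)
    t_low <- 1 / p$f
  }
  if (is.null(window)) window <- t_low
  mid <- sqrt(lo * hi)
  os_fps <- os_fixed_points(p)
  os_hi <- max(os_fps[os_fps$stability == "STABLE", "os"])
  os_un <- os_fps[os_fps$stability == "UNSTABLE", "os"]
  os_un <- if (length(os_un)) max(os_un) else os_hi / 2
  # calibration sweep: un-opposed collapse within half a window
  t_exp <- window / 2
  amplitude <- NA_real_
  for (a in 10^seq(-0.5, 6, by = 0.25)) {
    os <- os_hi
    h <- t_exp / 400
    for (i in 1:400) os <- os + (os_production(os, p) -
                                 p$d_os * (1 + a) * os) * h
    if (os < 0.9 * os_un) { amplitude <- a; break }
  }
  if (is.na(amplitude))
    stop("signal calibration failed: no amplitude on the sweep grid ",
         "collapses [OS] within the window", call. = FALSE)
  sig <- signal_params(t_on = 0, t_off = window, amplitude = amplitude,
                       k_gate = mid^gamma_gate, gamma_gate = gamma_gate)
  cache_set(key, sig)
}
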