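# State classification, residence-time statistics, population summaries.

th_unit <- state_thresholds(low_exit = 1.25, high_exit = 0.8, cut = 1)

test_that("square wave crossing both thresholds yields one record per level", {
  # 4 HIGH plateaus interleaved with 3 LOW plateaus: 7 records
  lev <- rep(c(2, 0.1), length.out = 7)
  tr <- data.frame(t = seq(0, 6.99, by = 0.01),
                   n = rep(lev, each = 100))
  rec <- classify_states(tr, th_unit, f = 1)
  expect_equal(nrow(rec), 7L)
  expect_equal(rec$state, rep(c("HIGH", "LOW"), length.out = 7))
  expect_equal(rec$censored, c(TRUE, rep(FALSE, 5), TRUE))
})

test_that("a constant high trajectory is one censored HIGH record", {
  tr <- data.frame(t = seq(0, 1, by = 0.01), n = rep(5, 101))
  rec <- classify_states(tr, th_unit, f = 1)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$state, "HIGH")
  expect_true(rec$censored)
  expect_equal(rec$duration, 1)
})

test_that("hysteresis suppresses chatter inside the band", {
  # oscillates between the thresholds: no transition may fire
  tr <- data.frame(t = seq(0, 1, by = 0.001),
                   n = 1 + 0.2 * sin(seq(0, 50, length.out = 1001)))
  rec <- classify_states(tr, th_unit, f = 1)
  expect_equal(nrow(rec), 1L)
})

test_that("residence summary: hand-computed mean, CV and normalization", {
  # LOW plateaus of 2 and 4 time units between HIGH stretches
  tt <- seq(0, 11.99, by = 0.01)
  n <- rep(2, length(tt))
  n[tt >= 1 & tt < 3] <- 0.1   # LOW, 2 units
  n[tt >= 5 & tt < 9] <- 0.1   # LOW, 4 units
  rec <- classify_states(data.frame(t = tt, n = n), th_unit, f = 270)
  expect_equal(rec$duration_normalized, 270 * rec$duration)
  rs <- residence_statistics(rec, state = "LOW")
  expect_equal(rs$LOW$n, 2L)
  expect_equal(rs$LOW$mean_raw, 3, tolerance = 1e-2)
  expect_equal(rs$LOW$cv, 1 / 3, tolerance = 1e-2)
  expect_equal(rs$LOW$mean_tau, 810, tolerance = 1)
  # the HIGH stretches are all censored (first/last) except the middle one
  expect_error(residence_statistics(rec[rec$censored, ], state = "LOW"),
               "censored")
})

test_that("sojourn durations partition the whole trajectory", {
  rec <- classify_states(fluct_long_traj)
  expect_equal(sum(rec$duration),
               max(fluct_long_traj$t) - min(fluct_long_traj$t),
               tolerance = 1e-8)
  # alternating states
  expect_true(all(rec$state[-1] != rec$state[-nrow(rec)]))
})

test_that("fraction_low is invariant to ordering and joint rescaling", {
  set.seed(9)
  snap <- c(rexp(200, 5), 10 + rnorm(300))
  f0 <- fraction_low(snap, cut = 1)
  expect_equal(fraction_low(sample(snap), cut = 1), f0)
  expect_equal(fraction_low(snap * 37, cut = 37), f0)
  expect_equal(f0, 200 / 500, tolerance = 0.05)
})

test_that("deterministic oscillation gives fixed residence times", {
  cfg <- sim_config(dt = 2e-3, t_end = 800, record_every = 5L, seed = 1)
  tr <- simulate_cell(osc, cfg, sigma = 0)
  rec <- classify_states(tr)
  lows <- rec[rec$state == "LOW" & !rec$censored, "duration"]
  highs <- rec[rec$state == "HIGH" & !rec$censored, "duration"]
  expect_gte(length(lows), 5L)
  expect_lt(stats::sd(lows) / mean(lows), 0.01)
  expect_lt(stats::sd(highs) / mean(highs), 0.01)
})

test_that("noise-driven LOW sojourns are exponential; oscillatory ones are not", {
  rec <- classify_states(fluct_long_traj)
  lows <- rec[rec$state == "LOW" & !rec$censored, "duration"]
  expect_gte(length(lows), 500L)
  cv <- sqrt(mean((lows - mean(lows))^2)) / mean(lows)
  expect_equal(cv, 1, tolerance = 0.2)
  # memorylessness: beyond the band-traversal scale (which distorts the
  # shortest sojourns) the conditional distribution is again exponential
  cc <- 0.5 * mean(lows)
  tl <- lows[lows > cc] - cc
  ks <- suppressWarnings(stats::ks.test(tl, "pexp", 1 / mean(tl)))
  expect_gt(ks$p.value, 0.01)
  # oscillation: narrowly peaked around the cycle's low dwell
  rec_o <- classify_states(osc_long_traj)
  lows_o <- rec_o[rec_o$state == "LOW" & !rec_o$censored, "duration"]
  cv_o <- sqrt(mean((lows_o - mean(lows_o))^2)) / mean(lows_o)
  expect_lt(cv_o, 0.5)
})

test_that("population histogram conserves cells and normalizes its density", {
  set.seed(11)
  snap <- c(rexp(300, 8), rlnorm(700, log(13), 0.4))
  ph <- population_histogram(snap)
  expect_equal(sum(ph$histogram$counts), 1000)
  dd <- ph$density
  area <- sum(diff(dd$n) * (dd$density[-1] + dd$density[-nrow(dd)]) / 2)
  expect_equal(area, 1, tolerance = 0.05)
  expect_true(ph$bimodal)
  # a point mass is unimodal
  ph1 <- population_histogram(rep(3, 50))
  expect_false(ph1$bimodal)
  expect_equal(ph1$n_modes, 1L)
})

test_that("stationary oscillation snapshot is bimodal on the density scale", {
  cfg <- sim_config(dt = 5e-3, t_end = 30, seed = 21, n_cells = 400)
  ens <- simulate_population(osc, cfg)
  ph <- population_histogram(ens)
  expect_true(ph$bimodal)
  # modes bracket the mode-separating cut: one below, one above
  cut <- nanogswitch:::nanog_separatrix(osc)
  expect_true(any(ph$modes < cut) && any(ph$modes > cut))
})

test_that("the Nanog-low fraction grows with the noise amplitude", {
  frac <- sapply(c(6, 18), function(s) {
    q <- fluct
    q$sigma <- s
    cfg <- sim_config(dt = 2e-4, t_end = 8, seed = 17, n_cells = 400)
    fraction_low(simulate_population(q, cfg))
  })
  expect_lt(frac[1], frac[2])
})

test_that("default thresholds wrap the unstable point with a hysteresis band", {
  th <- default_thresholds(fluct)
  cut <- nanogswitch:::nanog_separatrix(fluct)
  expect_equal(th$cut, cut)
  expect_lt(th$high_exit, cut)
  expect_gt(th$low_exit, cut)
  expect_error(state_thresholds(1, 2), "high_exit <= low_exit")
  expect_error(classify_states(data.frame(t = 0, n = 1), th_unit, f = 1),
               "2 samples")
})
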