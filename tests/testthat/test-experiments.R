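# Presets, configuration round trips, and the two discriminating in-silico
# experiments (sorting, differentiation challenge).

test_that("built-in presets carry the published parameter values exactly", {
  p <- preset("fluctuation")
  expect_identical(
    unlist(p[c("u", "s1", "s2", "s3", "s4", "k1", "k2", "k3", "k4",
               "gamma_os", "gamma_n", "d_o", "d_s", "d_os", "d_n",
               "sigma", "f")], use.names = FALSE),
    c(0.03, 50, 50, 0.1, 14, 10, 10, 10, 10, 1, 2, 1, 1, 1, 1, 12, 270))
  expect_true(all(is.na(unlist(p[c("s5", "s6", "k5", "gamma_x", "d_x")]))))
  q <- preset("oscillation")
  expect_identical(
    unlist(q[c("s4", "s5", "s6", "k4", "k5", "gamma_x", "d_x",
               "sigma", "f")], use.names = FALSE),
    c(30, 10.08, 4.74, 2, 10, 1, 0.2, 0.3, 16))
  expect_error(preset("typo"), "valid names")
})

test_that("YAML round trip preserves a parameter set including n/a fields", {
  path <- tempfile(fileext = ".yaml")
  write_params_yaml(fluct, path)
  p2 <- read_params_yaml(path)
  expect_equal(unclass(p2), unclass(fluct))
  path2 <- tempfile(fileext = ".yaml")
  write_params_yaml(osc, path2)
  expect_equal(unclass(read_params_yaml(path2)), unclass(osc))
})

test_that("sorted fluctuation subpopulations relax without overshoot", {
  cfg <- sim_config(dt = 2e-4, t_end = 8, seed = 41, n_cells = 400)
  r_hi <- run_sort_and_reestablish(fluct, cfg, "HIGH")
  expect_false(r_hi$overshoot)
  expect_equal(r_hi$fraction_low[1], 0)   # purified high cells
  # the low fraction relaxes back toward the equilibrium fraction
  expect_equal(tail(r_hi$fraction_low, 1), r_hi$equilibrium_fraction,
               tolerance = 0.6)
  r_lo <- run_sort_and_reestablish(fluct, cfg, "LOW")
  expect_false(r_lo$overshoot)
  expect_equal(r_lo$fraction_low[1], 1)
})

test_that("sorted oscillation subpopulations overshoot while re-synchronizing", {
  cfg <- sim_config(dt = 5e-3, t_end = 30, seed = 41, n_cells = 400)
  r_lo <- run_sort_and_reestablish(osc, cfg, "LOW")
  expect_true(r_lo$overshoot)
  expect_gt(r_lo$overshoot_magnitude, 0.1)  # pronounced for sorted-low cells
  r_hi <- run_sort_and_reestablish(osc, cfg, "HIGH")
  # both series converge to the same equilibrium fraction
  expect_equal(tail(r_lo$fraction_low, 1), tail(r_hi$fraction_low, 1),
               tolerance = 0.5)
  expect_equal(mean(tail(r_lo$fraction_low, 10)),
               r_lo$equilibrium_fraction, tolerance = 0.5)
})

test_that("a one-cell sort gives a degenerate 0/1 series and no claims", {
  cfg <- sim_config(dt = 1e-3, t_end = 2, seed = 3, n_cells = 1)
  r <- run_sort_and_reestablish(fluct, cfg, "HIGH", t_follow = 0.5,
                                n_record = 10)
  expect_true(all(r$fraction_low %in% c(0, 1)))
  expect_true(is.na(r$overshoot))
})

test_that("differentiation outcome depends on the Nanog state at signal time", {
  sig <- default_signal(fluct)
  cfg <- sim_config(dt = 1e-5, t_end = 20, record_every = 10L, seed = 4)
  r_low <- run_differentiation_challenge(fluct, cfg, sig, "LOW",
                                         t_follow = 2)
  expect_equal(r_low$outcome, "DIFFERENTIATED")
  expect_lt(r_low$final_os, r_low$os_unstable)
  r_high <- run_differentiation_challenge(fluct, cfg, sig, "HIGH",
                                          t_follow = 2)
  expect_equal(r_high$outcome, "MAINTAINED")
  expect_gt(r_high$final_os, 50)
})

test_that("oscillation challenge collapses only in the low phase and locks", {
  sig <- default_signal(osc)
  cfg <- sim_config(dt = 2e-3, t_end = 300, record_every = 4L, seed = 4)
  r_low <- run_differentiation_challenge(osc, cfg, sig, "LOW",
                                         t_follow = 30)
  expect_equal(r_low$outcome, "DIFFERENTIATED")
  expect_equal(r_low$post_signal_transitions, 0L)
  r_high <- run_differentiation_challenge(osc, cfg, sig, "HIGH",
                                          t_follow = 30)
  expect_equal(r_high$outcome, "MAINTAINED")
})

test_that("a zero-amplitude signal never differentiates", {
  sig0 <- signal_params(0, 0.01, amplitude = 0, k_gate = 2)
  cfg <- sim_config(dt = 1e-4, t_end = 10, record_every = 10L, seed = 4)
  r <- run_differentiation_challenge(fluct, cfg, sig0, "LOW", t_follow = 1)
  expect_equal(r$outcome, "MAINTAINED")
})

test_that("an unreachable trigger state raises an informative error", {
  sig <- default_signal(fluct)
  cfg <- sim_config(dt = 1e-4, t_end = 0.02, seed = 1)
  expect_error(
    run_differentiation_challenge(fluct, cfg, sig, "LOW"),
    "never reached")
})

test_that("reproduce() writes an idempotent figure bundle", {
  dir1 <- file.path(tempdir(), "bundle1")
  files1 <- reproduce("fig2", dir1, seed = 5, scale = 0.02)
  md5_a <- tools::md5sum(files1)
  files2 <- reproduce("fig2", dir1, seed = 5, scale = 0.02)
  md5_b <- tools::md5sum(files2)
  expect_identical(md5_a, md5_b)
  expect_true(all(file.exists(files1)))
  expect_error(reproduce("fig9"), "unknown figure id")
})
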