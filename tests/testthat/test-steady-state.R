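# Fixed points, stability, bifurcation scans and limit-cycle detection.

test_that("OS fixed points match the analytic quadratic", {
  fps <- os_fixed_points(fluct)
  # 75 os = (10 + os)^2 plus the origin
  expected <- sort(c(0, (55 - sqrt(2625)) / 2, (55 + sqrt(2625)) / 2))
  expect_equal(fps$os, expected, tolerance = 1e-7)
  expect_equal(fps$stability, c("STABLE", "UNSTABLE", "STABLE"))
})

test_that("no production leaves only the stable origin", {
  q <- fluct
  q$u <- 0
  fps <- os_fixed_points(q)
  expect_equal(nrow(fps), 1L)
  expect_equal(fps$os, 0)
  expect_equal(fps$stability, "STABLE")
})

test_that("upper OS root grows with the production ceiling", {
  q <- fluct
  q$u <- 10 * q$u
  up0 <- max(os_fixed_points(fluct)$os)
  up1 <- max(os_fixed_points(q)$os)
  expect_gt(up1, up0)
})

test_that("Nanog fixed points at os* = 0 follow the quadratic formula", {
  fps <- nanog_fixed_points(fluct, os_star = 0)
  expected <- sort(c(0, (14 - sqrt(14^2 - 40)) / 2, (14 + sqrt(14^2 - 40)) / 2))
  expect_equal(fps$n, expected, tolerance = 1e-8)
  expect_equal(fps$stability, c("STABLE", "UNSTABLE", "STABLE"))
  # below the fold a single root survives
  q <- fluct
  q$s4 <- 5
  expect_equal(nanog_fixed_points(q, os_star = 0)$n, 0)
})

test_that("fluctuation preset separates the stable Nanog states by ~2 decades", {
  fps <- nanog_fixed_points(fluct)
  st <- fps[fps$stability == "STABLE", "n"]
  expect_equal(length(st), 2L)
  expect_equal(log10(max(st) / min(st)), 2.14, tolerance = 0.05)
  expect_equal(min(st), 0.0974, tolerance = 1e-2)
  expect_equal(max(st), 13.34, tolerance = 1e-2)
  un <- fps[fps$stability == "UNSTABLE", "n"]
  expect_equal(un, 0.6475, tolerance = 1e-3)
})

test_that("reported fixed points satisfy the model RHS to 1e-8", {
  osv <- max(os_fixed_points(fluct)$os)
  for (n in nanog_fixed_points(fluct)$n) {
    d <- core_rhs(c(os = osv, n = n), fluct)
    expect_lt(abs(d[["n"]]), 1e-8)
  }
  ofp <- oscillation_fixed_points(osc)
  osv2 <- max(os_fixed_points(osc)$os)
  for (i in seq_len(nrow(ofp))) {
    d <- oscillation_rhs(c(os = osv2, n = ofp$n[i], x = ofp$x[i]), osc)
    expect_lt(abs(d[["n"]]), 1e-7)
    expect_lt(abs(d[["x"]]), 1e-7)
  }
})

test_that("stability labels agree with perturbed sigma = 0 integration", {
  fps <- nanog_fixed_points(fluct)
  osv <- max(os_fixed_points(fluct)$os)
  st <- fps[fps$stability == "STABLE", "n"]
  un <- fps[fps$stability == "UNSTABLE", "n"]
  for (n0 in st) {
    cfg <- sim_config(dt = 1e-3, t_end = 5, seed = 1,
                      init = c(os = osv, n = n0 * 1.05))
    tr <- simulate_cell(fluct, cfg, sigma = 0)
    expect_lt(abs(tr$n[nrow(tr)] - n0), abs(n0 * 0.05))
  }
  # a nudge off the unstable point grows toward one of the stable states
  cfg <- sim_config(dt = 1e-3, t_end = 8, seed = 1,
                    init = c(os = osv, n = un * 1.05))
  tr <- simulate_cell(fluct, cfg, sigma = 0)
  expect_gt(abs(tr$n[nrow(tr)] - un), 5 * abs(un * 0.05))
})

test_that("scan in s4 finds a bistable window containing the operating point", {
  b <- scan_bifurcation(fluct, "s4", seq(0, 30, by = 0.5))
  expect_false(is.null(b$bistable_window))
  expect_gte(14, b$bistable_window[1])
  expect_lte(14, b$bistable_window[2])
  # refinement moves the edges by less than one coarse grid step
  b2 <- scan_bifurcation(fluct, "s4", seq(0, 30, by = 0.25))
  expect_lt(max(abs(b2$bistable_window - b$bistable_window)), 0.5 + 1e-9)
})

test_that("scan-based roots equal dense brute-force roots on random draws", {
  set.seed(7)
  for (i in 1:20) {
    q <- fluct
    q$s4 <- runif(1, 1, 30)
    q$k4 <- runif(1, 1, 20)
    q$s3 <- runif(1, 0, 0.5)
    osv <- runif(1, 0, 60)
    fps <- nanog_fixed_points(q, os_star = osv)
    # independent brute force: sign changes of the steady-state function on
    # a fine fixed grid, refined by bisection
    f <- function(n) q$s3 * osv / (q$k3 + osv) +
      q$s4 * n^2 / (q$k4 + n^2) - n
    g <- seq(1e-9, 40, length.out = 200001)
    v <- f(g)
    idx <- which(v[-length(v)] * v[-1] < 0)
    brute <- vapply(idx, function(j) {
      lo <- g[j]; hi <- g[j + 1]
      for (k in 1:60) {
        mid <- (lo + hi) / 2
        if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
      }
      (lo + hi) / 2
    }, numeric(1))
    if (f(1e-12) == 0) brute <- c(0, brute)
    expect_equal(nrow(fps), length(brute))
    expect_equal(fps$n, sort(brute), tolerance = 1e-6)
  }
})

test_that("bistability onset at os* = 0 matches s4 = 2 sqrt(k4) to 1e-6", {
  k4 <- fluct$k4
  onset <- function(s4) {
    q <- fluct
    q$s4 <- s4
    nrow(nanog_fixed_points(q, os_star = 0, n_grid = 2e5)) >= 3
  }
  lo <- 6; hi <- 7
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (onset(mid)) hi <- mid else lo <- mid
  }
  expect_equal((lo + hi) / 2, 2 * sqrt(k4), tolerance = 1e-6)
})

test_that("scan in s6 finds an oscillatory window containing 4.74", {
  b <- scan_bifurcation(osc, "s6", sort(c(4.74, seq(0.5, 10, by = 0.5))))
  expect_false(is.null(b$oscillatory_window))
  expect_gte(4.74, b$oscillatory_window[1])
  expect_lte(4.74, b$oscillatory_window[2])
})

test_that("limit cycle is an attractor: period independent of the start", {
  lc1 <- find_limit_cycle(osc, init = c(n = 0.5, x = 5), t_max = 1500)
  lc2 <- find_limit_cycle(osc, init = c(n = 20, x = 30), t_max = 1500)
  expect_true(lc1$found && lc2$found)
  expect_lt(abs(lc1$period - lc2$period) / lc1$period, 0.01)
  expect_gt(lc1$n_max / max(lc1$n_min, 1e-6), 50)  # wide excursion
})

test_that("no cycle without the repressor or without repression", {
  expect_false(find_limit_cycle(fluct)$found)
  q <- osc
  q$s6 <- 0
  expect_false(find_limit_cycle(q)$found)
})

test_that("degenerate one-point grid yields a branch without window claims", {
  b <- scan_bifurcation(fluct, "s4", 14)
  expect_equal(unique(b$points$parameter), 14)
  expect_null(b$bistable_window)
  expect_error(scan_bifurcation(fluct, "s4", c(-1, 2)), "non-negative")
})
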