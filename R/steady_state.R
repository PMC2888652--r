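# Deterministic analysis: fixed points, linear stability, one-parameter
# bifurcation scans, limit-cycle characterization. The OS subsystem is
# autonomous, so the analysis computes OS* once and then treats the 1-D
# (fluctuation) or 2-D (oscillation) Nanog(/X) subsystem at fixed OS*.

stability_label <- function(eigenvalues, tol = 1e-8) {
  re <- Re(eigenvalues)
  if (any(abs(re) <= tol))
    stop("MARGINAL fixed point: eigenvalue real part within +/-", tol,
         " of zero; stability cannot be assigned", call. = FALSE)
  if (all(re < 0)) return("STABLE")
  if (all(re > 0)) return("UNSTABLE")
  "SADDLE"
}

# Dense sign-change bracketing on [0, upper] followed by uniroot refinement.
# Returns sorted roots; f must be continuous and is evaluated vectorized
# where possible. A root exactly on a grid point (e.g. the origin) is kept
# as-is.
bracket_roots <- function(f, upper, n_grid = 4000, tol = 1e-10) {
  grid <- seq(0, upper, length.out = n_grid + 1)
  v <- f(grid)
  if (length(v) != length(grid)) v <- vapply(grid, f, numeric(1))
  if (any(!is.finite(v)))
    stop("root scan failed: non-finite values; bracketing report: upper=",
         upper, ", first bad point at ", grid[which(!is.finite(v))[1]],
         call. = FALSE)
  idx <- which(v[-length(v)] * v[-1] < 0)
  roots <- vapply(idx, function(i)
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = tol)$root, numeric(1))
  exact <- grid[v == 0]
  sort(unique(c(roots, exact)))
}

num_deriv <- function(f, x, h = NULL) {
  if (is.null(h)) h <- max(1e-6, 1e-6 * abs(x))
  (f(x + h) - f(max(x - h, 0))) / (h + min(h, x))
}

#' Fixed points of the Oct4-Sox2 subsystem
#'
#' The heterodimer equation is autonomous (independent of Nanog and X), so
#' its fixed points are the non-negative roots of a scalar steady-state
#' equation. With the default parameters there are three: the origin
#' (stable; both production Hill terms vanish), an unstable intermediate
#' root, and the stable upper root near 53 molecules at which a pluripotent
#' cell operates.
#'
#' @param p a `scenario_params` object.
#' @return A data frame with columns `os`, `eigenvalue` (the scalar
#'   derivative of the right-hand side at the root) and `stability`.
#' @export
os_fixed_points <- function(p) {
  g <- function(os) os_production(os, p) - p$d_os * os
  upper <- max(10 * p$u * p$s1 * p$s2 / (p$d_o * p$d_s * p$d_os), 1)
  roots <- bracket_roots(g, upper)   # the origin is always an exact root
  ev <- vapply(roots, function(r) num_deriv(g, r), numeric(1))
  data.frame(os = roots, eigenvalue = ev,
             stability = vapply(ev, function(e) stability_label(e), character(1)))
}

# Highest stable OS fixed point: the operating point of the network.
os_operating_point <- function(p) {
  fps <- os_fixed_points(p)
  st <- fps[fps$stability == "STABLE", "os"]
  max(st)
}

#' Fixed points of the Nanog subsystem at fixed Oct4-Sox2 level
#'
#' Roots of `s3 H(os*; k3) + s4 H(n; k4) - d_n n = 0` with linear stability
#' from the scalar derivative. Inside the bistable window there are exactly
#' three roots: a low state close to the basal OS-mediated transcription, an
#' unstable separatrix, and a high state sustained by the auto-regulation;
#' with the fluctuation defaults the stable states are separated by about
#' two orders of magnitude.
#'
#' @param p a `scenario_params` object.
#' @param os_star Oct4-Sox2 concentration at which the Nanog subsystem is
#'   evaluated; defaults to the upper stable OS fixed point.
#' @param n_grid resolution of the sign-change scan; raise it to resolve
#'   near-fold root pairs (their separation shrinks like the square root of
#'   the distance to the fold).
#' @return A data frame with columns `n`, `eigenvalue`, `stability`.
#' @export
nanog_fixed_points <- function(p, os_star = NULL, n_grid = 4000) {
  if (is.null(os_star)) os_star <- os_operating_point(p)
  stopifnot(os_star >= 0)
  basal <- p$s3 * hill(os_star, p$k3, p$gamma_os)
  f <- function(n) basal + p$s4 * hill(n, p$k4, p$gamma_n) - p$d_n * n
  upper <- 10 * (p$s3 + p$s4) / p$d_n
  roots <- bracket_roots(f, upper, n_grid = n_grid)
  ev <- vapply(roots, function(r) num_deriv(f, r), numeric(1))
  data.frame(n = roots, eigenvalue = ev,
             stability = vapply(ev, function(e) stability_label(e), character(1)))
}

# The unstable Nanog fixed point (separatrix) used as classification cut.
# For the oscillation scenario this is the interior unstable focus of the
# (N, X) subsystem.
nanog_separatrix <- function(p, os = NULL) {
  if (is.null(os)) os <- os_operating_point(p)
  fps <- if (p$scenario == "oscillation") oscillation_fixed_points(p, os)
         else nanog_fixed_points(p, os)
  nm <- if ("n" %in% names(fps)) "n" else stop("no Nanog column")
  un <- fps[fps$stability != "STABLE", nm]
  if (length(un) == 0)
    stop("no unstable Nanog fixed point for this parameter set", call. = FALSE)
  # with multiple non-stable points take the interior one (largest below the
  # top stable state, or the single unstable focus)
  un[length(un)]
}

#' Fixed points of the (Nanog, X) subsystem at fixed Oct4-Sox2 level
#'
#' Solves the two-dimensional activator/repressor subsystem of the
#' oscillation scenario on the X nullcline (`x = s5 H(n; k5) / d_x`) and
#' classifies each root by the eigenvalues of the 2x2 Jacobian. In the
#' oscillatory window the only interior fixed point is an unstable focus
#' surrounded by the limit cycle.
#'
#' @param p an oscillation-scenario `scenario_params` object.
#' @param os_star Oct4-Sox2 level; defaults to the upper stable OS root.
#' @return A data frame with columns `n`, `x`, `re_max` (largest eigenvalue
#'   real part) and `stability`.
#' @export
oscillation_fixed_points <- function(p, os_star = NULL) {
  if (p$scenario != "oscillation")
    stop("oscillation_fixed_points requires an oscillation-scenario ",
         "parameter set", call. = FALSE)
  if (is.null(os_star)) os_star <- os_operating_point(p)
  basal <- p$s3 * hill(os_star, p$k3, p$gamma_os)
  x_null <- function(n) p$s5 * hill(n, p$k5, p$gamma_n) / p$d_x
  f <- function(n) {
    x <- x_null(n)
    ng <- n^p$gamma_n
    basal + p$s4 * ng / (p$k4 + ng + p$s6 * x^p$gamma_x) - p$d_n * n
  }
  upper <- 10 * (p$s3 + p$s4) / p$d_n
  roots <- bracket_roots(f, upper)
  res <- lapply(roots, function(n) {
    x <- x_null(n)
    J <- nx_jacobian(p, basal, n, x)
    ev <- eigen(J, only.values = TRUE)$values
    data.frame(n = n, x = x, re_max = max(Re(ev)),
               stability = stability_label(ev))
  })
  do.call(rbind, res)
}

# Jacobian of the (n, x) subsystem at fixed OS (basal = s3*H(os*)).
nx_jacobian <- function(p, basal, n, x) {
  gn <- p$gamma_n; gx <- p$gamma_x
  ng <- n^gn; xg <- x^gx
  den <- p$k4 + ng + p$s6 * xg
  dfdn <- p$s4 * gn * n^(gn - 1) * (p$k4 + p$s6 * xg) / den^2 - p$d_n
  dfdx <- -p$s4 * ng * p$s6 * gx * x^(gx - 1) / den^2
  kg <- p$k5 + ng
  dgdn <- p$s5 * gn * n^(gn - 1) * p$k5 / kg^2
  dgdx <- -p$d_x
  matrix(c(dfdn, dfdx, dgdn, dgdx), 2, 2, byrow = TRUE)
}

#' Characterize the limit cycle of the oscillation scenario
#'
#' Integrates the deterministic (sigma = 0) Nanog/X subsystem at fixed OS*
#' past its transient and extracts the oscillation period and the extrema of
#' both concentrations from successive Nanog maxima. Returns a "no cycle"
#' result (`found = FALSE`) instead of an error when the trajectory settles
#' on a fixed point, so bifurcation scans can proceed through the window
#' edges.
#'
#' Results for the default arguments are cached per parameter set, since the
#' long integration is re-used by ensemble initialization and the experiment
#' drivers.
#'
#' @param p a `scenario_params` object (oscillation scenario for a cycle to
#'   exist; the fluctuation scenario yields `found = FALSE` since it has no
#'   X species and hence no negative feedback).
#' @param init optional initial condition `c(n, x)`.
#' @param t_max integration length (time units); the first half is discarded
#'   as transient.
#' @return An object of class `limit_cycle`: a list with `found`, `period`,
#'   `n_min`, `n_max`, `x_min`, `x_max`.
#' @export
find_limit_cycle <- function(p, init = c(n = 1, x = 1), t_max = 2000) {
  default_call <- identical(init, c(n = 1, x = 1)) && t_max == 2000
  key <- paste0("lc:", params_key(p))
  if (default_call) {
    hit <- cache_get(key)
    if (!is.null(hit)) return(hit)
  }
  res <- find_limit_cycle_impl(p, init, t_max)
  if (default_call) cache_set(key, res)
  res
}

find_limit_cycle_impl <- function(p, init, t_max) {
  if (p$scenario != "oscillation" || is.na(p$s6))
    return(structure(list(found = FALSE, period = NA_real_,
                          n_min = NA_real_, n_max = NA_real_,
                          x_min = NA_real_, x_max = NA_real_),
                     class = "limit_cycle"))
  osv <- os_operating_point(p)
  basal <- p$s3 * hill(osv, p$k3, p$gamma_os)
  rhs <- function(t, y, parms) {
    n <- max(y[1], 0); x <- max(y[2], 0)
    ng <- n^p$gamma_n
    list(c(basal + p$s4 * ng / (p$k4 + ng + p$s6 * x^p$gamma_x) - p$d_n * n,
           p$s5 * hill(n, p$k5, p$gamma_n) - p$d_x * x))
  }
  times <- seq(0, t_max, by = 0.01)
  sol <- deSolve::ode(c(n = init[[1]], x = init[[2]]), times, rhs, NULL,
                      method = "lsoda")
  half <- sol[sol[, 1] > t_max / 2, ]
  n <- half[, 2]; x <- half[, 3]
  amp <- max(n) - min(n)
  if (amp < 1e-4 * max(max(n), 1))
    return(structure(list(found = FALSE, period = NA_real_,
                          n_min = NA_real_, n_max = NA_real_,
                          x_min = NA_real_, x_max = NA_real_),
                     class = "limit_cycle"))
  dn <- diff(n)
  pk <- which(dn[-length(dn)] > 0 & dn[-1] <= 0) + 1
  pk <- pk[n[pk] > min(n) + 0.5 * amp]   # major maxima only
  if (length(pk) < 3)
    return(structure(list(found = FALSE, period = NA_real_,
                          n_min = NA_real_, n_max = NA_real_,
                          x_min = NA_real_, x_max = NA_real_),
                     class = "limit_cycle"))
  periods <- diff(half[pk, 1])
  # closure check: keep full cycles between the first and last major maximum
  seg <- seq(pk[1], pk[length(pk)])
  structure(list(found = TRUE, period = mean(periods),
                 period_cv = stats::sd(periods) / mean(periods),
                 n_min = min(n[seg]), n_max = max(n[seg]),
                 x_min = min(x[seg]), x_max = max(x[seg])),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  if (!x$found) cat("no limit cycle detected\n")
  else cat(sprintf(
    "limit cycle: period %.3f, n in [%.4f, %.3f], x in [%.3f, %.3f]\n",
    x$period, x$n_min, x$n_max, x$x_min, x$x_max))
  invisible(x)
}

#' One-parameter bifurcation scan
#'
#' Scans the Nanog fixed-point structure along a grid of the auto-regulatory
#' transcription rate `s4` (fluctuation scenario: folds delimiting the
#' bistable window) or of the repression strength `s6` (oscillation
#' scenario: Hopf instability delimiting the oscillatory window, detected by
#' the sign of the largest eigenvalue real part of the (N, X) Jacobian at
#' the interior fixed point, with limit-cycle extrema computed inside the
#' window).
#'
#' @param p a `scenario_params` object.
#' @param parameter `"s4"` or `"s6"`.
#' @param grid sorted ascending non-negative parameter values.
#' @param cycles logical; for `s6` scans also integrate the limit cycle at
#'   each oscillatory grid value to record its extrema (slower).
#' @return An object of class `bifurcation_branch`: a list with the scan
#'   table (`points`), the scanned grid, and the detected
#'   `bistable_window` / `oscillatory_window` (range or NULL).
#' @export
scan_bifurcation <- function(p, parameter = c("s4", "s6"), grid,
                             cycles = FALSE) {
  parameter <- match.arg(parameter)
  if (any(grid < 0) || is.unsorted(grid))
    stop("grid must be sorted ascending and non-negative", call. = FALSE)
  osv <- os_operating_point(p)
  pts <- list(); window <- NULL
  if (parameter == "s4") {
    nstable <- integer(length(grid))
    for (i in seq_along(grid)) {
      q <- p; q$s4 <- grid[i]
      fps <- nanog_fixed_points(q, osv)
      nstable[i] <- sum(fps$stability == "STABLE")
      pts[[i]] <- data.frame(parameter = grid[i],
                             branch_id = seq_len(nrow(fps)),
                             type = ifelse(fps$stability == "STABLE",
                                           "fp_stable", "fp_unstable"),
                             os = osv, n = fps$n, x = NA_real_,
                             period = NA_real_)
    }
    in_win <- nstable >= 2
    if (any(in_win) && length(grid) > 1)
      window <- range(grid[in_win])
  } else {
    if (p$scenario != "oscillation")
      stop("s6 scans require an oscillation-scenario parameter set",
           call. = FALSE)
    oscillatory <- logical(length(grid))
    for (i in seq_along(grid)) {
      q <- p; q$s6 <- grid[i]
      fps <- oscillation_fixed_points(q, osv)
      interior <- fps[fps$n > 1e-6, , drop = FALSE]
      # Hopf criterion: every interior fixed point repelling
      oscillatory[i] <- nrow(interior) > 0 && all(interior$re_max > 0)
      pts[[i]] <- data.frame(parameter = grid[i],
                             branch_id = seq_len(nrow(fps)),
                             type = ifelse(fps$stability == "STABLE",
                                           "fp_stable", "fp_unstable"),
                             os = osv, n = fps$n, x = fps$x,
                             period = NA_real_)
      if (cycles && oscillatory[i]) {
        lc <- find_limit_cycle(q)
        if (lc$found)
          pts[[i]] <- rbind(pts[[i]], data.frame(
            parameter = grid[i], branch_id = nrow(fps) + 1:2,
            type = c("cycle_min", "cycle_max"), os = osv,
            n = c(lc$n_min, lc$n_max), x = c(lc$x_min, lc$x_max),
            period = lc$period))
      }
    }
    if (any(oscillatory) && length(grid) > 1)
      window <- range(grid[oscillatory])
  }
  structure(list(parameter_name = parameter,
                 parameter_values = grid,
                 points = do.call(rbind, pts),
                 bistable_window = if (parameter == "s4") window else NULL,
                 oscillatory_window = if (parameter == "s6") window else NULL),
            class = "bifurcation_branch")
}

#' @export
print.bifurcation_branch <- function(x, ...) {
  cat("bifurcation scan in", x$parameter_name, "over",
      length(x$parameter_values), "grid values\n")
  w <- x$bistable_window %||% x$oscillatory_window
  if (!is.null(w))
    cat(sprintf("  %s window: [%g, %g]\n",
                if (is.null(x$bistable_window)) "oscillatory" else "bistable",
                w[1], w[2]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a bifurcation scan to CSV
#'
#' Columns: `parameter`, `branch_id`, `type` (`fp_stable`, `fp_unstable`,
#' `cycle_min`, `cycle_max`), `os`, `n`, `x`, `period`.
#'
#' @param branch a `bifurcation_branch` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bifurcation_csv <- function(branch, path) {
  stopifnot(inherits(branch, "bifurcation_branch"))
  utils::write.csv(branch$points, path, row.names = FALSE)
  invisible(path)
}

# Per-session cache for expensive deterministic results keyed by the full
# parameter set.
.cache <- new.env(parent = emptyenv())

params_key <- function(p) {
  paste(vapply(unclass(p), function(v) paste(format(v, digits = 17),
                                             collapse = ","), character(1)),
        collapse = "|")
}

cache_get <- function(key) {
  if (exists(key, envir = .cache, inherits = FALSE))
    get(key, envir = .cache, inherits = FALSE)
  else NULL
}

cache_set <- function(key, value) {
  assign(key, value, envir = .cache)
  invisible(value)
}
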