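# Summary statistics of trajectories and population snapshots: state
# classification with hysteresis, residence-time records, the Nanog-low
# fraction, and population histograms/density estimates.

#' State-classification thresholds
#'
#' A hysteresis band for classifying a Nanog trajectory into LOW and HIGH
#' sojourns: a LOW cell becomes HIGH only when its Nanog level rises above
#' `low_exit`, and a HIGH cell becomes LOW only when it falls below
#' `high_exit` (`high_exit <= low_exit`). The band suppresses spurious
#' transitions from noise chatter around a single cut.
#'
#' @param low_exit concentration above which a LOW cell becomes HIGH.
#' @param high_exit concentration below which a HIGH cell becomes LOW.
#' @param cut single-observation cut (snapshot classification); defaults to
#'   the geometric mid-point of the band.
#' @return An object of class `state_thresholds`.
#' @seealso [default_thresholds()] for the model-derived defaults.
#' @export
state_thresholds <- function(low_exit, high_exit,
                             cut = sqrt(low_exit * high_exit)) {
  if (!is.numeric(low_exit) || !is.numeric(high_exit) ||
      high_exit > low_exit || high_exit < 0)
    stop("thresholds must satisfy 0 <= high_exit <= low_exit", call. = FALSE)
  structure(list(low_exit = low_exit, high_exit = high_exit, cut = cut),
            class = "state_thresholds")
}

#' Model-derived default thresholds
#'
#' Places the hysteresis band symmetrically in log-concentration around the
#' unstable Nanog fixed point (the natural separatrix between the basins;
#' for the oscillation scenario, the interior unstable focus), with a +/-25%
#' band: `low_exit = 1.25 * n_u`, `high_exit = n_u / 1.25`. The
#' single-observation cut is the unstable point itself.
#'
#' @param p a `scenario_params` object.
#' @param band half-width of the hysteresis band as a factor (0.25 = +/-25%).
#' @return A `state_thresholds` object.
#' @export
default_thresholds <- function(p, band = 0.25) {
  n_u <- nanog_separatrix(p)
  state_thresholds(low_exit = n_u * (1 + band),
                   high_exit = n_u / (1 + band),
                   cut = n_u)
}

#' Classify a trajectory into LOW/HIGH sojourns
#'
#' Runs the hysteresis state machine over the Nanog component of a
#' trajectory and returns one record per contiguous sojourn. The first and
#' last records are flagged censored (their true duration is truncated by
#' the observation window). Durations are reported both in raw model time
#' and on the normalized scale tau = f * t.
#'
#' @param traj a `trajectory` (or any data frame with columns `t` and `n`).
#' @param th a [state_thresholds()] object.
#' @param f time-normalization factor; defaults to the trajectory's
#'   parameter set, else 1.
#' @return A data frame of class `residence_records` with columns `state`
#'   (`"LOW"`/`"HIGH"`), `t_enter`, `t_exit`, `duration`,
#'   `duration_normalized`, `censored`.
#' @export
classify_states <- function(traj, th = NULL, f = NULL) {
  if (is.null(th)) {
    p <- attr(traj, "params")
    if (is.null(p)) stop("no thresholds given and trajectory carries no ",
                         "parameter set", call. = FALSE)
    th <- default_thresholds(p)
  }
  stopifnot(inherits(th, "state_thresholds"))
  if (is.null(f)) {
    p <- attr(traj, "params")
    f <- if (!is.null(p)) p$f else 1
  }
  tt <- traj$t; n <- traj$n
  if (length(n) < 2) stop("trajectory must have at least 2 samples",
                          call. = FALSE)
  # vectorized state machine: +1 events (cross above low_exit), -1 events
  # (cross below high_exit); state changes only on the opposite event
  up <- n > th$low_exit
  down <- n < th$high_exit
  state0 <- if (n[1] >= th$cut) 1L else 0L
  ev <- integer(length(n)); ev[up] <- 1L; ev[down] <- -1L
  # carry the most recent event forward; before any event the state is state0
  pos <- cummax(ifelse(ev != 0L, seq_along(ev), 0L))
  lastev <- ifelse(pos == 0L, 0L, ev[pmax(pos, 1L)])
  states <- ifelse(lastev == 0L, state0, as.integer(lastev == 1L))
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  t_enter <- tt[starts]; t_exit <- c(tt[utils::head(ends, -1L) + 1L],
                                     tt[length(tt)])
  rec <- data.frame(
    state = ifelse(r$values == 1L, "HIGH", "LOW"),
    t_enter = t_enter, t_exit = t_exit,
    duration = t_exit - t_enter,
    censored = FALSE)
  rec$duration_normalized <- f * rec$duration
  rec$censored[c(1L, nrow(rec))] <- TRUE
  rec <- rec[, c("state", "t_enter", "t_exit", "duration",
                 "duration_normalized", "censored")]
  class(rec) <- c("residence_records", "data.frame")
  attr(rec, "thresholds") <- th
  attr(rec, "f") <- f
  rec
}

#' Fraction of Nanog-low cells in a population snapshot
#'
#' Classifies every cell of a snapshot by a single cut (no hysteresis is
#' possible on one observation) and returns the LOW fraction. The default
#' cut is the unstable Nanog fixed point separating the two basins (or, for
#' the oscillation scenario, the interior unstable focus of the
#' activator/repressor subsystem).
#'
#' @param snapshot numeric vector of Nanog concentrations, or an `ensemble`.
#' @param cut classification cut; a number, or `NULL` to derive it from the
#'   ensemble's parameter set.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_low <- function(snapshot, cut = NULL) {
  if (inherits(snapshot, "ensemble")) {
    if (is.null(cut)) cut <- nanog_separatrix(snapshot$params)
    snapshot <- snapshot$snapshot$n
  }
  if (length(snapshot) == 0) stop("snapshot is empty", call. = FALSE)
  if (is.null(cut)) stop("a classification cut is required", call. = FALSE)
  mean(snapshot < cut)
}

#' Residence-time summary statistics
#'
#' Mean (raw and normalized time), coefficient of variation and a binned
#' histogram of uncensored sojourn durations, per state. Censored sojourns
#' are excluded from the moments and reported as a count. The CV uses the
#' population standard deviation (divisor n). An exponential residence
#' distribution - the signature of memoryless noise-driven switching - has
#' CV ~ 1; deterministic oscillation gives narrowly peaked durations with
#' CV << 1.
#'
#' @param records a `residence_records` data frame from [classify_states()].
#' @param state `"LOW"`, `"HIGH"`, or both.
#' @param breaks histogram breaks passed to [hist()].
#' @return A list (class `residence_summary`) keyed by state, each entry a
#'   list with `state`, `n`, `mean_raw`, `mean_tau`, `cv`, `censored_n`,
#'   `histogram`.
#' @export
residence_statistics <- function(records, state = c("LOW", "HIGH"),
                                 breaks = "Sturges") {
  stopifnot(is.data.frame(records))
  f <- attr(records, "f") %||% 1
  out <- lapply(state, function(s) {
    rs <- records[records$state == s, , drop = FALSE]
    unc <- rs[!rs$censored, , drop = FALSE]
    if (nrow(unc) == 0)
      stop("all ", s, " sojourns are censored; no residence statistics",
           call. = FALSE)
    d <- unc$duration
    m <- mean(d)
    cv <- sqrt(mean((d - m)^2)) / m
    list(state = s, n = nrow(unc), mean_raw = m, mean_tau = f * m, cv = cv,
         censored_n = sum(rs$censored),
         histogram = graphics::hist(d, breaks = breaks, plot = FALSE))
  })
  names(out) <- state
  class(out) <- "residence_summary"
  out
}

#' @export
print.residence_summary <- function(x, ...) {
  for (s in x) {
    cat(sprintf(
      "%-4s state: n=%d uncensored (+%d censored), mean %.4g (%.3g tau), CV %.3f\n",
      s$state, s$n, s$censored_n, s$mean_raw, s$mean_tau, s$cv))
  }
  invisible(x)
}

#' Population histogram and density estimate of Nanog levels
#'
#' Bins a population snapshot and estimates a smooth density with a Gaussian
#' kernel on log10-scaled concentrations, with a small offset so that
#' clamped zero values participate. The default bandwidth is a quarter
#' decade: the two expression states sit about two decades apart, so this
#' suppresses within-mode sampling wiggles while keeping the modes separate
#' (a data-driven Silverman bandwidth is attracted to the dominant mode's
#' spread and produces spurious maxima). The density is reported back on the
#' concentration scale (so it integrates to one there), and the number of
#' density maxima provides a bimodality flag - the model's analogue of the
#' two-peaked flow-cytometry profile of a heterogeneous ES-cell population.
#'
#' @param snapshot numeric vector of Nanog concentrations, or an `ensemble`.
#' @param breaks histogram breaks (passed to [hist()]).
#' @param offset additive offset (molecules) for the log transform; should
#'   be below the Nanog-low scale.
#' @param bw kernel bandwidth in log10 units.
#' @return A list of class `population_histogram`: `histogram` (counts
#'   conserve the number of cells), `density` (data frame `n`, `density`),
#'   `n_modes`, `bimodal`, `modes` (concentrations of the density maxima).
#' @export
population_histogram <- function(snapshot, breaks = 50, offset = 0.01,
                                 bw = 0.25) {
  if (inherits(snapshot, "ensemble")) snapshot <- snapshot$snapshot$n
  if (length(snapshot) == 0) stop("snapshot is empty", call. = FALSE)
  h <- graphics::hist(snapshot, breaks = breaks, plot = FALSE)
  y <- log10(snapshot + offset)
  d <- stats::density(y, bw = bw)
  conc <- 10^d$x - offset
  # back-transform: p_n(n) = p_y(log10(n+off)) / ((n+off) ln 10)
  dens <- d$y / ((conc + offset) * log(10))
  keep <- conc >= 0
  dd <- data.frame(n = conc[keep], density = dens[keep])
  # plateau-robust interior maxima
  nn <- length(d$y)
  left <- c(-Inf, d$y[-nn]); right <- c(d$y[-1], -Inf)
  ymax <- which(d$y > left & d$y >= right)
  ymax <- ymax[ymax > 1 & ymax < nn]
  # ignore maxima carrying negligible height
  ymax <- ymax[d$y[ymax] > 0.05 * max(d$y)]
  modes <- 10^d$x[ymax] - offset
  structure(list(histogram = h, density = dd,
                 n_modes = length(ymax), bimodal = length(ymax) >= 2,
                 modes = modes),
            class = "population_histogram")
}

#' @export
print.population_histogram <- function(x, ...) {
  cat(sprintf("population histogram: %d cells, %d density mode(s)%s\n",
              sum(x$histogram$counts), x$n_modes,
              if (x$bimodal) " (bimodal)" else ""))
  invisible(x)
}

#' Write residence records to CSV / summary to JSON
#'
#' @param records a `residence_records` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_residence_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
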