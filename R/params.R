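#' Construct a scenario parameter set
#'
#' A `scenario_params` object holds the full rate/constant set of the
#' pluripotency network model for one scenario. In the `"fluctuation"`
#' scenario the network consists of the auto-regulating Oct4-Sox2 heterodimer
#' (concentration `[OS]`) and Nanog (`[N]`), with Gaussian white noise on the
#' Nanog equation driving transitions between the two stable Nanog states. In
#' the `"oscillation"` scenario a Nanog-activated transcriptional repressor X
#' (`[X]`) is added, turning the Nanog subsystem into an activator/repressor
#' oscillator; the X-specific parameters (`s5`, `s6`, `k5`, `gamma_x`, `d_x`)
#' are not applicable to the fluctuation scenario and are stored as `NA`.
#'
#' Units: `u` is a complex-formation rate (1/(molecules x time)), `s1..s6`
#' transcription/repression rates (molecules/time, except `s6` which weighs
#' the repressor occupancy), `k1..k5` apparent dissociation constants
#' (molecules^gamma, see [hill()]), `d_*` first-order degradation rates
#' (1/time), `sigma` the noise amplitude of the Nanog stochastic term, and
#' `f` the dimensionless time-normalization factor defining the normalized
#' time scale tau = f * t on which the mean Nanog-low residence time is 1.
#'
#' @param scenario `"fluctuation"` or `"oscillation"`.
#' @param u,s1,s2,s3,s4,s5,s6,k1,k2,k3,k4,k5 rates and constants (see above).
#' @param gamma_os,gamma_n,gamma_x Hill coefficients (>= 1).
#' @param d_o,d_s,d_os,d_n,d_x degradation rates (1/time).
#' @param sigma noise amplitude of the Nanog stochastic term.
#' @param f time-normalization factor.
#' @return A validated object of class `scenario_params`.
#' @seealso [preset()] for the built-in default parameter sets.
#' @export
scenario_params <- function(scenario = c("fluctuation", "oscillation"),
                            u = 0.03, s1 = 50, s2 = 50, s3 = 0.1, s4 = 14,
                            s5 = NA_real_, s6 = NA_real_,
                            k1 = 10, k2 = 10, k3 = 10, k4 = 10, k5 = NA_real_,
                            gamma_os = 1, gamma_n = 2, gamma_x = NA_real_,
                            d_o = 1, d_s = 1, d_os = 1, d_n = 1, d_x = NA_real_,
                            sigma = 12, f = 270) {
  scenario <- match.arg(scenario)
  p <- list(u = u, s1 = s1, s2 = s2, s3 = s3, s4 = s4, s5 = s5, s6 = s6,
            k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
            gamma_os = gamma_os, gamma_n = gamma_n, gamma_x = gamma_x,
            d_o = d_o, d_s = d_s, d_os = d_os, d_n = d_n, d_x = d_x,
            sigma = sigma, f = f, scenario = scenario)
  class(p) <- "scenario_params"
  validate_scenario_params(p)
  p
}

#' Validate a scenario parameter set
#'
#' Checks non-negativity of all rates and constants, Hill coefficients >= 1,
#' and presence of the X-specific parameters in the oscillation scenario.
#' Called by [scenario_params()]; exported so that parameter sets read from
#' configuration files can be re-checked.
#'
#' @param p a `scenario_params` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_scenario_params <- function(p) {
  stopifnot(inherits(p, "scenario_params"))
  core <- c("u", "s1", "s2", "s3", "s4", "k1", "k2", "k3", "k4",
            "d_o", "d_s", "d_os", "d_n", "sigma", "f")
  xpar <- c("s5", "s6", "k5", "gamma_x", "d_x")
  for (nm in core) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", nm, "' must be a single non-negative number",
           call. = FALSE)
  }
  for (nm in c("gamma_os", "gamma_n")) {
    if (!is.numeric(p[[nm]]) || is.na(p[[nm]]) || p[[nm]] < 1)
      stop("Hill coefficient '", nm, "' must be >= 1", call. = FALSE)
  }
  if (p$scenario == "oscillation") {
    for (nm in xpar) {
      v <- p[[nm]]
      if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
        stop("oscillation scenario requires parameter '", nm, "'",
             call. = FALSE)
    }
    if (p$gamma_x < 1)
      stop("Hill coefficient 'gamma_x' must be >= 1", call. = FALSE)
  }
  invisible(p)
}

#' Built-in default parameter sets
#'
#' Returns the default parameter set for one of the two scenarios. The
#' fluctuation set places the Nanog subsystem in its bistable window
#' (`s4 = 14`, noise `sigma = 12`); the oscillation set adds the repressor X
#' with `s4 = 30`, `s5 = 10.08`, `s6 = 4.74`, `k4 = 2`, `k5 = 10`,
#' `d_x = 0.2` and a small noise term `sigma = 0.3` that randomizes the
#' oscillation phase without causing the state transitions itself.
#'
#' @param name `"fluctuation"` or `"oscillation"`.
#' @return A `scenario_params` object.
#' @examples
#' preset("fluctuation")$s4   # 14
#' preset("oscillation")$s6   # 4.74
#' @export
preset <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("fluctuation", "oscillation"))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid names are 'fluctuation' and 'oscillation'", call. = FALSE)
  switch(name,
    fluctuation = scenario_params("fluctuation"),
    oscillation = scenario_params("oscillation",
                                  s4 = 30, s5 = 10.08, s6 = 4.74,
                                  k4 = 2, k5 = 10,
                                  gamma_x = 1, d_x = 0.2,
                                  sigma = 0.3, f = 16))
}

#' Differentiation-signal parameters
#'
#' Parameters of the hypothetical differentiation-inducing signal Y acting on
#' the Oct4-Sox2 production. The signal is active on the window
#' `[t_on, t_off)` with strength `amplitude`, and is blocked by Nanog through
#' a decreasing Hill gate: the effective signal is
#' `amplitude * (1 - H(n; k_gate, gamma_gate))`, so a Nanog-high cell
#' (`n >> k_gate^(1/gamma_gate)`) shields the network while a Nanog-low cell
#' is exposed (the double-negative "gate-keeper" feedback).
#'
#' @param t_on,t_off signal window (time units), `t_off > t_on >= 0`.
#' @param amplitude signal strength (dimensionless, >= 0).
#' @param k_gate Nanog occupancy constant of the gate (molecules^gamma_gate).
#' @param gamma_gate gating Hill coefficient (>= 1).
#' @return An object of class `signal_params`.
#' @export
signal_params <- function(t_on, t_off, amplitude, k_gate = 2, gamma_gate = 1) {
  if (!is.numeric(t_on) || !is.numeric(t_off) || t_on < 0 || t_off <= t_on)
    stop("signal window must satisfy t_off > t_on >= 0", call. = FALSE)
  if (amplitude < 0 || k_gate < 0)
    stop("amplitude and k_gate must be >= 0", call. = FALSE)
  if (gamma_gate < 1) stop("gamma_gate must be >= 1", call. = FALSE)
  structure(list(t_on = t_on, t_off = t_off, amplitude = amplitude,
                 k_gate = k_gate, gamma_gate = gamma_gate),
            class = "signal_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("Scenario parameter set:", x$scenario, "\n")
  num <- x[setdiff(names(x), "scenario")]
  v <- unlist(num)
  cat(paste0("  ", format(names(v), width = 9), format(v)), sep = "\n")
  invisible(x)
}

#' Read or write a parameter set as YAML
#'
#' Parameter sets are serialized with their field names as keys (`u`,
#' `s1`..`s6`, `k1`..`k5`, `gamma_os`, `gamma_n`, `gamma_x`, `d_o`, `d_s`,
#' `d_os`, `d_n`, `d_x`, `sigma`, `f`, `scenario`); `NA` fields are written
#' as the string `"n/a"`.
#'
#' @param p a `scenario_params` object.
#' @param path file path.
#' @return `read_params_yaml` returns a validated `scenario_params` object;
#'   `write_params_yaml` returns `path` invisibly.
#' @export
write_params_yaml <- function(p, path) {
  stopifnot(inherits(p, "scenario_params"))
  out <- lapply(unclass(p), function(v) if (is.numeric(v) && is.na(v)) "n/a" else v)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- lapply(raw, function(v) if (identical(v, "n/a")) NA_real_ else v)
  p <- do.call(scenario_params, raw)
  p
}
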