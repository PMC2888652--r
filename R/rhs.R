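#' Hill response function
#'
#' Saturating transcriptional response `H(c; k, gamma) = c^gamma / (k + c^gamma)`.
#' Note the convention: `k` is an *apparent* dissociation constant carrying
#' units molecules^gamma, i.e. the half-maximal concentration is
#' `k^(1/gamma)`. With `k = 10` and `gamma = 2` (the Nanog dimer
#' auto-regulation) half-max activation occurs at sqrt(10) ~ 3.16 molecules.
#' The alternative convention `c^gamma / (k^gamma + c^gamma)` would shift
#' every fixed point; this package uses the additive-`k` form throughout.
#'
#' @param c concentration (>= 0), vectorized.
#' @param k apparent dissociation constant (molecules^gamma).
#' @param gamma Hill coefficient (>= 1).
#' @return Response in `[0, 1)`.
#' @export
hill <- function(c, k, gamma) {
  cg <- c^gamma
  cg / (k + cg)
}

check_state <- function(state, need = c("os", "n")) {
  if (is.list(state)) state <- unlist(state)
  if (is.null(names(state)) || !all(need %in% names(state)))
    stop("state must be a named vector with components ",
         paste(need, collapse = ", "), call. = FALSE)
  s <- state[need]
  if (any(!is.finite(s)) || any(s < 0))
    stop("state concentrations must be finite and non-negative ",
         "(negative input signals an integrator bug)", call. = FALSE)
  s
}

# Production rate of the Oct4-Sox2 heterodimer. The monomers are assumed in
# quasi-steady state with their own OS-activated transcription (rates s1, s2,
# decays d_o, d_s), so the complex forms at
#   u * (s1/d_o) H(os;k1) * (s2/d_s) H(os;k2),
# bounded above by u*s1*s2/(d_o*d_s).
os_production <- function(os, p) {
  p$u * (p$s1 / p$d_o) * (p$s2 / p$d_s) *
    hill(os, p$k1, p$gamma_os) * hill(os, p$k2, p$gamma_os)
}

# Nanog production at heterodimer level os, Nanog level n and repressor level
# x (x = 0 recovers the core network). The OS activation (proximal promoter)
# and the dimer-mediated auto-regulation (distal enhancer) act independently
# and therefore add. X competes for binding sites of the auto-regulatory
# response, entering the denominator weighted by s6.
nanog_production <- function(os, n, x, p) {
  s6x <- if (is.na(p$s6) || is.na(p$gamma_x)) 0 else p$s6 * x^p$gamma_x
  ng <- n^p$gamma_n
  p$s3 * hill(os, p$k3, p$gamma_os) + p$s4 * ng / (p$k4 + ng + s6x)
}

#' Deterministic right-hand side of the core network
#'
#' Time derivatives of the Oct4-Sox2 heterodimer and Nanog concentrations:
#' \deqn{d[OS]/dt = u (s_1/d_O)(s_2/d_S) H([OS];k_1) H([OS];k_2) - d_{OS} [OS]}
#' \deqn{d[N]/dt = s_3 H([OS];k_3) + s_4 H([N];k_4) - d_N [N]}
#' with `H` the Hill function of [hill()] (coefficients `gamma_os` and
#' `gamma_n` respectively). The OS equation is autonomous: the heterodimer
#' settles at a stable level independent of Nanog, which then provides a
#' constant basal activation of Nanog transcription.
#'
#' @param state named numeric vector with components `os` and `n`
#'   (molecules); must be non-negative.
#' @param p a `scenario_params` object.
#' @return Named numeric vector `c(os = d[OS]/dt, n = d[N]/dt)`.
#' @export
core_rhs <- function(state, p) {
  s <- check_state(state, c("os", "n"))
  os <- s[["os"]]; n <- s[["n"]]
  c(os = os_production(os, p) - p$d_os * os,
    n = nanog_production(os, n, 0, p) - p$d_n * n)
}

#' Deterministic right-hand side of the oscillation network
#'
#' Extends [core_rhs()] by the transcriptional repressor X, which occupies
#' binding sites at the Nanog promoter (competitive repression of the Nanog
#' auto-regulation) and is itself activated by the Nanog dimer:
#' \deqn{d[N]/dt = s_3 H([OS];k_3) +
#'       s_4 [N]^{\gamma_N} / (k_4 + [N]^{\gamma_N} + s_6 [X]^{\gamma_X}) - d_N [N]}
#' \deqn{d[X]/dt = s_5 [N]^{\gamma_N} / (k_5 + [N]^{\gamma_N}) - d_X [X]}
#' At `x = 0` the Nanog equation reduces exactly to the core form. The
#' repressive action is attached to the auto-regulatory term: X competing
#' with the activating Nanog dimer for the enhancer is what annihilates the
#' Nanog-high branch once X has accumulated, producing the relaxation
#' oscillation; `s6` carries the repressor weight (no separate dissociation
#' constant exists for X occupancy).
#'
#' @param state named numeric vector with components `os`, `n`, `x`.
#' @param p a `scenario_params` object with all X parameters present.
#' @return Named numeric vector `c(os = , n = , x = )` of time derivatives.
#' @export
oscillation_rhs <- function(state, p) {
  if (any(is.na(c(p$s5, p$s6, p$k5, p$gamma_x, p$d_x))))
    stop("oscillation_rhs requires the X parameters s5, s6, k5, gamma_x, d_x",
         call. = FALSE)
  s <- check_state(state, c("os", "n", "x"))
  os <- s[["os"]]; n <- s[["n"]]; x <- s[["x"]]
  c(os = os_production(os, p) - p$d_os * os,
    n = nanog_production(os, n, x, p) - p$d_n * n,
    x = p$s5 * hill(n, p$k5, p$gamma_n) - p$d_x * x)
}

#' Right-hand side with a gated differentiation signal
#'
#' Adds the differentiation signal Y to the scenario's deterministic
#' right-hand side. Inside the window `[t_on, t_off)` the effective signal is
#' `y_eff = amplitude * (1 - H(n; k_gate, gamma_gate))`: high Nanog blocks
#' the signal, low Nanog admits it. The admitted signal represses the
#' heterodimer by scaling its removal term to `d_os * (1 + y_eff)`, so a
#' sufficiently strong un-opposed signal drives `[OS]` below its unstable
#' fixed point within a fraction of a Nanog-low sojourn, after which the
#' heterodimer production (which needs `[OS]` itself) cannot recover and the
#' complex collapses to the origin. Repression of the removal side rather
#' than the production side is what lets the collapse outrun the fast
#' Nanog switching of the fluctuation scenario, whose Nanog-low sojourns
#' are three orders of magnitude shorter than `1/d_os`.
#'
#' @param state named numeric vector (`os`, `n`, and `x` for the oscillation
#'   scenario).
#' @param p a `scenario_params` object.
#' @param sig a [signal_params()] object.
#' @param t current time (determines whether the window is active).
#' @return Named derivative vector, same layout as the un-signalled RHS.
#' @export
signal_rhs <- function(state, p, sig, t) {
  stopifnot(inherits(sig, "signal_params"))
  base <- if (p$scenario == "oscillation") oscillation_rhs(state, p)
          else core_rhs(state, p)
  y_eff <- if (t >= sig$t_on && t < sig$t_off) {
    n <- if (is.list(state)) state$n else state[["n"]]
    sig$amplitude * (1 - hill(n, sig$k_gate, sig$gamma_gate))
  } else 0
  if (y_eff > 0) {
    os <- if (is.list(state)) state$os else state[["os"]]
    base[["os"]] <- os_production(os, p) - p$d_os * (1 + y_eff) * os
  }
  base
}

# Parameter vector handed to the compiled integrator and to deSolve closures.
# Layout must match src/em.cpp.
pack_params <- function(p, sig = NULL) {
  xp <- function(v) if (is.na(v)) 0 else v
  c(p$u, p$s1, p$s2, p$s3, p$s4, xp(p$s5), xp(p$s6),
    p$k1, p$k2, p$k3, p$k4, xp(p$k5),
    p$gamma_os, p$gamma_n, xp(p$gamma_x),
    p$d_o, p$d_s, p$d_os, p$d_n, xp(p$d_x),
    as.numeric(p$scenario == "oscillation"),
    if (is.null(sig)) c(0, 0, 0, 1, 1)
    else c(sig$t_on, sig$t_off, sig$amplitude, sig$k_gate, sig$gamma_gate))
}
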