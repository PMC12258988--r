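#' Construct a model state vector
#'
#' The eight dynamical variables of the model: membrane potential, six gating
#' variables and the intracellular Ca2+ concentration. With
#' `gates_at_steady_state = TRUE` (the default when gates are not given),
#' every gate is set to its steady-state value at `V`.
#'
#' @param V membrane potential, mV.
#' @param Ca intracellular Ca2+ concentration, mM (>= 0).
#' @param gates optional named numeric vector with entries `h_NaF`, `m_Kdr`,
#'   `m_Kv1.2`, `h_Kv1.2`, `m_CaL`, `h_CaL`, each in \[0, 1\].
#' @return Named numeric vector of class `mn_state`, length 8.
#' @examples
#' mn_state(-80)
#' @export
mn_state <- function(V, Ca = 0, gates = NULL) {
  if (Ca < -1e-12) stop("Ca must be >= 0")
  if (is.null(gates)) {
    gates <- vapply(dynamic_gates(), steady_state, numeric(1), V = V)
  } else {
    gates <- gates[dynamic_gates()]
    if (anyNA(gates)) stop("gates must name all six dynamic gating variables")
    if (any(gates < -1e-9 | gates > 1 + 1e-9))
      stop("gating variables must lie in [0, 1]")
  }
  s <- c(V = V, gates, Ca = max(Ca, 0))
  names(s) <- state_names()
  class(s) <- "mn_state"
  s
}

as_state <- function(x) {
  if (inherits(x, "mn_state")) return(x)
  x <- unlist(x)
  if (length(x) != 8) stop("a model state has exactly 8 components")
  if (!is.null(names(x)) && all(state_names() %in% names(x)))
    x <- x[state_names()]
  names(x) <- state_names()
  class(x) <- "mn_state"
  x
}

#' Membrane currents at a given state
#'
#' Evaluates all eight transmembrane currents (outward positive, uA/cm2) at a
#' state. The instantaneous activations `m_NaF` and `m_NaP` are computed from
#' `V`; `I_CAN` and `I_KCa` use Michaelis saturation `Ca / (Ca + K)` with
#' half-activation `K_CAN` and `K_d` respectively.
#'
#' @param state an `mn_state` (or coercible length-8 vector).
#' @param params an `mn_params` object.
#' @return Named numeric vector: `I_NaF`, `I_NaP`, `I_Kdr`, `I_Kv1.2`,
#'   `I_CaL`, `I_CAN`, `I_KCa`, `I_L`.
#' @examples
#' p <- mn_params()
#' compute_currents(mn_state(-80), p)
#' @export
compute_currents <- function(state, params) {
  stopifnot(inherits(params, "mn_params"))
  s <- as_state(state)
  .mn_currents_cpp(unclass(s), 0, param_vector(params))
}

#' Right-hand side of the model ODE system
#'
#' Time derivative of the full state: the current-balance equation for `V`
#' (sum of membrane currents, outward positive, plus injected current, divided
#' by the capacitance), first-order relaxation `tau(V) dx/dt = x_inf(V) - x`
#' for each dynamic gate, and the calcium balance
#' `dCa/dt = -f * alpha * I_CaL + k_CICR * Ca - Ca / tau_Ca`.
#'
#' @param t time, ms (the system is autonomous; kept for ODE-solver
#'   signatures).
#' @param state an `mn_state` (or coercible length-8 vector).
#' @param I_inj injected current, uA/cm2.
#' @param params an `mn_params` object.
#' @return Named numeric vector of derivatives, same layout as the state.
#' @examples
#' p <- mn_params()
#' mn_rhs(0, mn_state(-80), 0, p)
#' @export
mn_rhs <- function(t, state, I_inj, params) {
  stopifnot(inherits(params, "mn_params"))
  s <- as_state(state)
  d <- .mn_rhs_cpp(t, unclass(s), I_inj, param_vector(params))
  names(d) <- state_names()
  d
}

# Ca2+ concentration at equilibrium for a clamped voltage: setting dCa/dt = 0
# gives Ca* = f * alpha * (-I_CaL(V)) * tau_eff (I_CaL is inward/negative at
# sub-reversal voltages, so Ca* >= 0).
equilibrium_ca <- function(V, params) {
  m <- steady_state("m_CaL", V)
  h <- steady_state("h_CaL", V)
  ICaL <- params$g_CaL * m * h * (V - params$E_Ca)
  ca <- params$f * params$alpha * (-ICaL) *
    effective_tau(params$k_CICR, params$tau_Ca)
  pmax(ca, 0)
}
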