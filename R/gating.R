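# Gating kinetics of the voltage-dependent channels.
#
# Each gate has a Boltzmann steady-state curve x_inf(V) = 1/(1+exp(-(V-Vh)/k))
# (k < 0 encodes inactivation curves) and either a voltage-dependent or a
# constant time constant. m_NaF and m_NaP are instantaneous (algebraic in V);
# h_NaP is identically 1 and is not a state variable.

gate_table <- function() {
  list(
    m_NaF    = list(vh = -35,   k = 7.8,  tau = NA,       instant = TRUE),
    h_NaF    = list(vh = -55,   k = -7,   tau = "h_NaF",   instant = FALSE),
    m_NaP    = list(vh = -53,   k = 3,    tau = NA,       instant = TRUE),
    m_Kdr    = list(vh = -28,   k = 15,   tau = "m_Kdr",   instant = FALSE),
    `m_Kv1.2` = list(vh = -46,  k = 6.9,  tau = "m_Kv1.2", instant = FALSE),
    `h_Kv1.2` = list(vh = -54,  k = -7.1, tau = "h_Kv1.2", instant = FALSE),
    m_CaL    = list(vh = -27.5, k = 5.7,  tau = 0.5,      instant = FALSE),
    h_CaL    = list(vh = -52.4, k = -5.2, tau = 18,       instant = FALSE)
  )
}

#' Steady-state activation/inactivation of a gate
#'
#' Boltzmann steady-state curve of the named gate, evaluated at membrane
#' potential `V`. Gates: `m_NaF`, `h_NaF`, `m_NaP`, `m_Kdr`, `m_Kv1.2`,
#' `h_Kv1.2`, `m_CaL`, `h_CaL`.
#'
#' @param gate gate name (see Details).
#' @param V membrane potential, mV (vectorised).
#' @return Open fraction in (0, 1).
#' @examples
#' steady_state("m_NaP", -53) # 0.5 at the half-activation voltage
#' @export
steady_state <- function(gate, V) {
  tb <- gate_table()
  g <- tb[[gate]]
  if (is.null(g)) stop("unknown gate: ", gate)
  1 / (1 + exp(-(V - g$vh) / g$k))
}

#' Voltage-dependent gating time constant
#'
#' Time constant of the named dynamic gate at membrane potential `V`.
#' `m_CaL` and `h_CaL` have constant time constants (0.5 and 18 ms);
#' `m_NaF` and `m_NaP` are instantaneous and have no time constant.
#'
#' @inheritParams steady_state
#' @return Time constant in ms (strictly positive).
#' @examples
#' time_constant("h_NaF", -50) # 15 ms: both exponentials equal 1
#' @export
time_constant <- function(gate, V) {
  tb <- gate_table()
  g <- tb[[gate]]
  if (is.null(g)) stop("unknown gate: ", gate)
  if (isTRUE(g$instant))
    stop("gate ", gate, " is instantaneous and has no time constant")
  if (is.numeric(g$tau)) return(rep_len(g$tau, length(V)))
  switch(g$tau,
    h_NaF = 30 / (exp((V + 50) / 15) + exp(-(V + 50) / 16)),
    m_Kdr = 7 / (exp((V + 40) / 40) + exp(-(V + 40) / 50)),
    `m_Kv1.2` = 2.44 + 18.387 /
      (exp(-(V - 25.645) / 21.633) + exp((V + 4.42) / 45.9)),
    `h_Kv1.2` = 74.74 /
      (0.00015 * exp(-(V + 13) / 15) + 0.06 / (1 + exp(-(V + 68) / 12))),
    stop("no time-constant rule for gate ", gate)
  )
}

# names of the dynamic state variables, in C++ layout order
state_names <- function() {
  c("V", "h_NaF", "m_Kdr", "m_Kv1.2", "h_Kv1.2", "m_CaL", "h_CaL", "Ca")
}

dynamic_gates <- function() state_names()[2:7]
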