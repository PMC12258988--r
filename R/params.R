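#' Model parameters for the motoneuron model
#'
#' Constructs the full parameter set of the single-compartment motoneuron
#' model: maximal conductances, reversal potentials, potassium concentrations,
#' Ca2+ handling constants and the L-type Ca2+ gating time constants. Defaults
#' are the published reference values; the modulatory conductances
#' (`g_NaP`, `g_Kv1.2`, `g_CAN`, `g_KCa`) default to zero and are switched on
#' per experiment.
#'
#' Units are fixed throughout the package: mV, ms, uA/cm2, mS/cm2, uF/cm2, mM.
#'
#' The potassium reversal potential is not a free field: it is derived from
#' `K_out`, `K_in` and `nernst_coeff` via [nernst_EK()] whenever the parameter
#' set is used.
#'
#' @param ... named overrides of the default fields (e.g. `g_CAN = 0.5`).
#'   Unknown names are an error.
#' @return An object of class `mn_params`: a named list of all model constants.
#' @examples
#' p <- mn_params(g_CAN = 0.5)
#' p$g_CAN
#' nernst_EK(p$K_out, p$K_in, p$nernst_coeff)
#' @export
mn_params <- function(...) {
  p <- mn_param_defaults()
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == "")))
    stop("all parameter overrides must be named")
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- lapply(over, as.numeric)
  class(p) <- "mn_params"
  validate_params(p)
  p
}

mn_param_defaults <- function() {
  list(
    C = 1,
    g_NaF = 120, g_Kdr = 100, g_NaP = 0, `g_Kv1.2` = 0,
    g_CaL = 0.05, g_CAN = 0, g_KCa = 0, g_L = 0.1,
    E_Na = 55, E_Ca = 80, E_CAN = 0, E_L = -80,
    K_out = 4, K_in = 140, nernst_coeff = 26.54,
    K_CAN = 0.74e-3, K_d = 0.2e-3,
    f = 0.01, alpha = 5e-4, k_CICR = 0.096, tau_Ca = 10,
    tau_CaL_m = 0.5, tau_CaL_h = 18
  )
}

validate_params <- function(p) {
  g <- c("g_NaF", "g_Kdr", "g_NaP", "g_Kv1.2", "g_CaL", "g_CAN", "g_KCa",
         "g_L")
  for (nm in g)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("conductance ", nm, " must be finite and >= 0")
  if (!is.finite(p$C) || p$C <= 0) stop("C must be > 0")
  if (p$K_out <= 0 || p$K_in <= 0)
    stop("potassium concentrations must be > 0")
  if (p$tau_Ca <= 0) stop("tau_Ca must be > 0")
  if (p$tau_CaL_m <= 0 || p$tau_CaL_h <= 0)
    stop("I_CaL gating time constants must be > 0")
  if (p$f < 0 || p$k_CICR < 0 || p$alpha < 0)
    stop("f, alpha and k_CICR must be >= 0")
  if (p$k_CICR >= 1 / p$tau_Ca)
    stop("k_CICR must be below 1/tau_Ca = ", format(1 / p$tau_Ca),
         " ms^-1: larger values give runaway calcium release")
  # published operating ranges; sweeps may probe the edges, so warn only
  if (p$`g_Kv1.2` > 10)
    warning("g_Kv1.2 = ", p$`g_Kv1.2`, " is outside the modelled range [0, 10]")
  if (p$K_out < 4 - 1e-12 || p$K_out > 12 + 1e-12)
    warning("K_out = ", p$K_out, " mM is outside the modelled range [4, 12]")
  invisible(p)
}

#' @export
print.mn_params <- function(x, ...) {
  cat("Motoneuron model parameters (mV-ms-uA/cm2-mS/cm2-mM):\n")
  nm <- names(x)
  v <- unlist(x)
  cat(paste0("  ", format(nm, width = 13), " = ", format(v)), sep = "\n")
  cat(sprintf("  (E_K = %.2f mV from K_out/K_in)\n",
              nernst_EK(x$K_out, x$K_in, x$nernst_coeff)))
  invisible(x)
}

#' Potassium Nernst (reversal) potential
#'
#' `E_K = coeff * ln(K_out / K_in)`. With the default coefficient of 26.54 mV
#' (RT/F near recording temperature) and natural logarithm.
#'
#' @param K_out,K_in extracellular and intracellular K+ concentration, mM.
#' @param coeff Nernst slope in mV (default 26.54).
#' @return Reversal potential in mV.
#' @examples
#' nernst_EK(4, 140) # about -94.4 mV
#' @export
nernst_EK <- function(K_out, K_in, coeff = 26.54) {
  if (any(K_out <= 0) || any(K_in <= 0))
    stop("ion concentrations must be positive")
  coeff * log(K_out / K_in)
}

#' Effective calcium clearance time constant under CICR
#'
#' Calcium-induced calcium release feeds calcium back into the cytosol at
#' rate `k_CICR * Ca`, so the linear part of the calcium balance relaxes with
#' `tau_eff = (1/tau_Ca - k_CICR)^-1` rather than the raw pump constant
#' `tau_Ca`. `k_CICR` must stay below `1/tau_Ca`; beyond that the calcium
#' concentration grows without bound.
#'
#' @param k_CICR CICR gain, ms^-1.
#' @param tau_Ca pump clearance time constant, ms.
#' @return Effective time constant in ms.
#' @examples
#' effective_tau(0.096, 10) # 250 ms
#' effective_tau(0, 10)     # no CICR: plain pump constant
#' @export
effective_tau <- function(k_CICR, tau_Ca) {
  if (tau_Ca <= 0) stop("tau_Ca must be > 0")
  if (any(k_CICR >= 1 / tau_Ca))
    stop("k_CICR >= 1/tau_Ca: runaway calcium regime, tau_eff undefined")
  1 / (1 / tau_Ca - k_CICR)
}

#' Current-to-concentration conversion factor from shell geometry
#'
#' The factor converting an inward Ca2+ current density (uA/cm2) into a rate
#' of change of concentration (mM/ms) in a thin shell under the membrane is
#' `alpha = 1 / (2 F delta)` with `F` Faraday's constant and `delta` the shell
#' thickness. Evaluated in the package unit system
#' (mM cm2 ms^-1 uA^-1).
#'
#' @param faraday Faraday constant, C/mol (default 9.648e4).
#' @param delta_um shell thickness in micrometres (default 0.1).
#' @return alpha in mM cm2 ms^-1 uA^-1.
#' @examples
#' alpha_from_shell() # about 5e-4
#' @export
alpha_from_shell <- function(faraday = 9.648e4, delta_um = 0.1) {
  delta_cm <- delta_um * 1e-4
  # 1 uA/cm2 = 1e-6 C/s/cm2 = 1e-9 C/ms/cm2; mol -> mmol gives 1e3
  # alpha [mM cm2 / (ms uA)] = 1e-9 * 1e3 * 1e3 / (2 F delta_cm)
  #   (C/ms per uA/cm2) * (mmol/C) * (1/cm) -> mmol/cm3 = mol/L = M; *1e3 -> mM
  1e-3 / (2 * faraday * delta_cm)
}

# fixed layout used by the C++ code
param_vector <- function(p) {
  stopifnot(inherits(p, "mn_params"))
  c(p$C, p$g_NaF, p$g_Kdr, p$g_NaP, p$`g_Kv1.2`, p$g_CaL, p$g_CAN, p$g_KCa,
    p$g_L, p$E_Na, p$E_Ca, p$E_CAN, p$E_L,
    nernst_EK(p$K_out, p$K_in, p$nernst_coeff),
    p$K_CAN, p$K_d, p$f, p$alpha, p$k_CICR, p$tau_Ca, p$tau_CaL_m, p$tau_CaL_h)
}

#' Modify a parameter set
#'
#' @param p an `mn_params` object.
#' @param ... named fields to change.
#' @return A new validated `mn_params` object.
#' @export
set_params <- function(p, ...) {
  stopifnot(inherits(p, "mn_params"))
  over <- list(...)
  if (length(over) == 0) return(p)
  do.call(mn_params, modifyList(unclass(p), over))
}

#' Read / write parameter sets as flat key-value config files
#'
#' Serialises an `mn_params` object to a flat YAML (or JSON) mapping whose
#' keys are exactly the parameter field names. On reading, defaults are
#' applied first and the file's keys layered on top; unknown keys are
#' rejected.
#'
#' @param p an `mn_params` object.
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_params()` returns an `mn_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "mn_params"))
  x <- lapply(unclass(p), as.numeric)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(x)) stop("config must be a key-value mapping")
  do.call(mn_params, x)
}
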