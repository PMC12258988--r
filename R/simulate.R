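#' Integrate the motoneuron model under a current program
#'
#' Adaptive Dormand-Prince 5(4) integration of the full 8-variable model with
#' dense output sampled on a fixed grid. Spike times (upward crossings of
#' `spike_threshold`, reported at the spike peak) are detected on the dense
#' solution as a by-product. Fully deterministic: identical inputs give
#' bitwise-identical traces.
#'
#' @param params an `mn_params` object.
#' @param program a `current_program`.
#' @param init initial state (`mn_state`); default is the resting state at the
#'   program's initial current (see [resting_state()]).
#' @param dt_out output sampling interval, ms (default 0.05, about 20 samples
#'   per ms, enough to resolve 1-2 ms action potentials).
#' @param rtol,atol relative/absolute local error tolerances
#'   (defaults 1e-8, 1e-10).
#' @param keep_trace if `FALSE`, the sampled trace is discarded and only spike
#'   times, final state and solver statistics are returned (memory-light mode
#'   used by long ramp protocols).
#' @param spike_threshold spike detection threshold, mV (default -10).
#' @param refractory minimal separation between threshold crossings, ms
#'   (default 2).
#' @return An object of class `mn_trace`: a data frame with columns `time_ms`,
#'   `V_mV`, the six gating variables, `Ca_mM` and `Iinj_uAcm2`, with
#'   attributes `spike_times`, `spike_iinj`, `final_state` and `solver`
#'   (tolerances and step counts). With `keep_trace = FALSE`, a list with the
#'   same attributes but no samples.
#' @examples
#' p <- mn_params()
#' tr <- simulate_program(p, current_program(50, 0), dt_out = 0.5)
#' range(tr$V_mV)
#' @export
simulate_program <- function(params, program, init = NULL, dt_out = 0.05,
                             rtol = 1e-8, atol = 1e-10, keep_trace = TRUE,
                             spike_threshold = -10, refractory = 2) {
  stopifnot(inherits(params, "mn_params"), inherits(program, "current_program"))
  if (is.null(init))
    init <- resting_state(params, I_inj = program$start[1])
  init <- as_state(init)
  res <- .mn_integrate_cpp(unclass(init), param_vector(params),
                           program_matrix(program),
                           dt_out, rtol, atol, keep_trace,
                           spike_threshold, refractory, scan_dt = 0.05)
  fin <- as_state(res$final_state)
  solver <- list(rtol = rtol, atol = atol, dt_out = dt_out,
                 n_accepted = res$n_accepted, n_rejected = res$n_rejected)
  if (!keep_trace) {
    out <- list(spike_times = res$spike_times, spike_iinj = res$spike_iinj,
                final_state = fin, solver = solver)
    class(out) <- "mn_sim_summary"
    return(out)
  }
  df <- data.frame(time_ms = res$time, res$states, res$iinj)
  names(df) <- c("time_ms", "V_mV", "h_NaF", "m_Kdr", "m_Kv1.2", "h_Kv1.2",
                 "m_CaL", "h_CaL", "Ca_mM", "Iinj_uAcm2")
  attr(df, "spike_times") <- res$spike_times
  attr(df, "spike_iinj") <- res$spike_iinj
  attr(df, "final_state") <- fin
  attr(df, "solver") <- solver
  class(df) <- c("mn_trace", "data.frame")
  df
}

#' Resting state of the model at a constant injected current
#'
#' Finds the stable hyperpolarized equilibrium (all gates at steady state, Ca
#' at its voltage-consistent equilibrium), refines it by a short relaxation
#' integration followed by root polishing, and verifies that the ODE residual
#' is below `residual_tol`. If no stable equilibrium exists at this current
#' (e.g. above the spiking onset threshold I_up), an error of class
#' `mn_no_rest` is thrown.
#'
#' @param params an `mn_params` object.
#' @param I_inj holding current, uA/cm2 (default 0).
#' @param V_guess optional initial voltage guess, mV; the stable equilibrium
#'   nearest the guess is returned (default: the most hyperpolarized one).
#' @param residual_tol acceptance bound on `max |d state/dt|` (default 1e-8).
#' @return An `mn_state` at rest.
#' @export
resting_state <- function(params, I_inj = 0, V_guess = NULL,
                          residual_tol = 1e-8) {
  eq <- find_equilibria(params, I_inj)
  stable <- Filter(function(e) e$classification == "stable-node", eq)
  if (length(stable) == 0) {
    stop(structure(class = c("mn_no_rest", "error", "condition"),
                   list(message = sprintf(
                     "no stable resting state at I_inj = %g uA/cm2", I_inj),
                     call = sys.call(-1))))
  }
  vs <- vapply(stable, function(e) e$state[["V"]], numeric(1))
  pick <- if (is.null(V_guess)) which.min(vs) else which.min(abs(vs - V_guess))
  s <- stable[[pick]]$state
  # short relaxation run confirms local stability and polishes transients
  relax <- simulate_program(params, current_program(200, I_inj), init = s,
                            dt_out = 10, keep_trace = FALSE)
  s <- relax$final_state
  # polish V at the fully relaxed gate configuration
  root <- tryCatch(
    uniroot(function(v) net_current_balance(v, I_inj, params),
            interval = s[["V"]] + c(-2, 2), tol = 1e-12),
    error = function(e) NULL)
  if (!is.null(root)) s <- equilibrium_state(root$root, params)
  resid <- max(abs(mn_rhs(0, s, I_inj, params)))
  if (resid > residual_tol)
    stop("resting-state residual ", format(resid), " exceeds ",
         format(residual_tol))
  s
}

#' Write / read a simulated trace as CSV
#'
#' Lossless round-trip of the sampled trace columns (`time_ms`, `V_mV`, the
#' six gates, `Ca_mM`, `Iinj_uAcm2`). Spike times and solver metadata are not
#' stored in the CSV.
#'
#' @param trace an `mn_trace`.
#' @param path CSV file path.
#' @return `read_trace()` returns an `mn_trace` (without solver metadata);
#'   `write_trace()` returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "data.frame"))
  df <- as.data.frame(trace)
  # full precision so that the round trip is lossless
  out <- df
  out[] <- lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else col)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("time_ms", "V_mV") %in% names(df)))
    stop("not a trace CSV: need at least time_ms and V_mV columns")
  class(df) <- c("mn_trace", "data.frame")
  df
}

#' @export
print.mn_trace <- function(x, ...) {
  cat(sprintf("Motoneuron trace: %d samples over %.4g ms, %d spike(s)\n",
              nrow(x), max(x$time_ms) - min(x$time_ms),
              length(attr(x, "spike_times"))))
  cat(sprintf("  V range [%.2f, %.2f] mV\n", min(x$V_mV), max(x$V_mV)))
  invisible(x)
}
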