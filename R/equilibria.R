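# Equilibrium analysis.
#
# At an equilibrium every gate sits on its steady-state curve and the calcium
# concentration at its voltage-consistent value Ca*(V) =
# f * alpha * (-I_CaL(V)) * tau_eff, so the fixed-point problem reduces to a
# scalar equation in V: the net current balance must vanish. Roots are
# bracketed on a voltage grid, refined by bisection/Brent, expanded to the
# full 8-dimensional state and classified by the eigenvalues of the
# numerically differentiated Jacobian.

equilibrium_state <- function(V, params) {
  mn_state(V, Ca = equilibrium_ca(V, params))
}

# dV/dt (times C) at the V-reduced equilibrium manifold
net_current_balance <- function(V, I_inj, params) {
  vapply(V, function(v) {
    s <- equilibrium_state(v, params)
    cur <- compute_currents(s, params)
    I_inj - sum(cur)
  }, numeric(1))
}

#' Find and classify the equilibria of the model
#'
#' Scans the reduced scalar current balance over a voltage grid, brackets sign
#' changes, refines each root, reconstructs the full state and classifies it
#' by the eigenvalues of the Jacobian (central finite differences with
#' per-variable scaled steps): `stable-node` (all real parts negative),
#' `saddle` (exactly one positive real part) or `unstable`.
#'
#' @param params an `mn_params` object.
#' @param I_inj injected current, uA/cm2.
#' @param V_range voltage bracket, mV (default `c(-100, 20)`).
#' @param V_step scan grid step, mV (default 0.5).
#' @param residual_tol maximal acceptable `max |d state/dt|` at a reported
#'   equilibrium (default 1e-8); roots that fail refinement are skipped with
#'   a warning.
#' @return A list of equilibrium points, each a list with elements `state`
#'   (`mn_state`), `I_inj`, `classification`, `eigenvalues` and `residual`.
#' @examples
#' eq <- find_equilibria(mn_params(), 0)
#' sapply(eq, `[[`, "classification")
#' @export
find_equilibria <- function(params, I_inj, V_range = c(-100, 20),
                            V_step = 0.5, residual_tol = 1e-8) {
  stopifnot(inherits(params, "mn_params"))
  vs <- seq(V_range[1], V_range[2], by = V_step)
  fv <- net_current_balance(vs, I_inj, params)
  out <- list()
  for (i in seq_len(length(vs) - 1)) {
    if (!is.finite(fv[i]) || !is.finite(fv[i + 1])) next
    if (fv[i] == 0) {
      root <- vs[i]
    } else if (fv[i] * fv[i + 1] < 0) {
      r <- tryCatch(
        uniroot(net_current_balance, c(vs[i], vs[i + 1]), I_inj = I_inj,
                params = params, tol = 1e-12),
        error = function(e) NULL)
      if (is.null(r)) {
        warning("root refinement failed in [", vs[i], ", ", vs[i + 1], "] mV")
        next
      }
      root <- r$root
    } else next
    st <- equilibrium_state(root, params)
    resid <- max(abs(mn_rhs(0, st, I_inj, params)))
    if (resid > residual_tol) {
      warning(sprintf("equilibrium near V = %.3f mV rejected (residual %g)",
                      root, resid))
      next
    }
    J <- mn_jacobian(st, I_inj, params)
    ev <- eigen(J, only.values = TRUE)$values
    npos <- sum(Re(ev) > 0)
    cls <- if (npos == 0) "stable-node" else if (npos == 1) "saddle"
           else "unstable"
    out[[length(out) + 1]] <- list(state = st, I_inj = I_inj,
                                   classification = cls, eigenvalues = ev,
                                   residual = resid)
  }
  out
}

#' Jacobian of the model right-hand side
#'
#' Central finite differences with steps scaled per variable (1e-4 mV for `V`,
#' 1e-7 for gates, relative 1e-6 with floor 1e-10 mM for Ca).
#'
#' @inheritParams mn_rhs
#' @return An 8x8 numeric matrix.
#' @export
mn_jacobian <- function(state, I_inj, params) {
  s <- as_state(state)
  hs <- c(1e-4, rep(1e-7, 6), max(1e-6 * abs(s[["Ca"]]), 1e-10))
  J <- matrix(0, 8, 8, dimnames = list(state_names(), state_names()))
  for (j in 1:8) {
    sp <- sm <- unclass(s)
    sp[j] <- sp[j] + hs[j]
    sm[j] <- sm[j] - hs[j]
    J[, j] <- (.mn_rhs_cpp(0, sp, I_inj, param_vector(params)) -
               .mn_rhs_cpp(0, sm, I_inj, param_vector(params))) / (2 * hs[j])
  }
  J
}

#' Characterise the attractor reached at a constant current
#'
#' Integrates for `settle` ms (discarded), then `window` ms, and summarises
#' the stationary regime: whether repetitive spiking persists, the voltage
#' range covered, and the mean firing frequency.
#'
#' @param params an `mn_params` object.
#' @param I_inj constant injected current, uA/cm2.
#' @param init initial state.
#' @param settle transient to discard, ms (default 3000).
#' @param window analysis window, ms (default 2000).
#' @param spike_threshold,refractory spike detection settings.
#' @param ... passed to [simulate_program()].
#' @return A list: `exists` (repetitive spiking in the window), `min_V`,
#'   `max_V` (mV over the window), `frequency` (Hz, `NA` if fewer than two
#'   spikes), `n_spikes`, `I_inj`, `final_state`.
#' @export
trace_limit_cycle <- function(params, I_inj, init, settle = 3000,
                              window = 2000, spike_threshold = -10,
                              refractory = 2, ...) {
  pre <- simulate_program(params, current_program(settle, I_inj), init = init,
                          keep_trace = FALSE,
                          spike_threshold = spike_threshold,
                          refractory = refractory, ...)
  tr <- simulate_program(params, current_program(window, I_inj),
                         init = pre$final_state, dt_out = 0.05,
                         spike_threshold = spike_threshold,
                         refractory = refractory, ...)
  st <- attr(tr, "spike_times")
  n <- length(st)
  freq <- if (n >= 2) 1000 * (n - 1) / (st[n] - st[1]) else NA_real_
  list(exists = n >= 2, min_V = min(tr$V_mV), max_V = max(tr$V_mV),
       frequency = freq, n_spikes = n, I_inj = I_inj,
       final_state = attr(tr, "final_state"))
}

#' Quasi-static continuation of rest and spiking branches
#'
#' Two sweeps across a sorted current grid. Ascending: starting from the
#' resting state at the lowest current, each step inherits the previous final
#' state, so the trajectory tracks the resting branch until it disappears
#' (fold). Descending: starting from the spiking regime at the highest
#' current, tracking the limit-cycle branch until spiking dies. Equilibria
#' are computed independently at each grid point. The coexistence interval of
#' the two branches approximates `[I_down, I_up]` at grid resolution.
#'
#' @param params an `mn_params` object.
#' @param I_grid sorted injected-current grid, uA/cm2.
#' @param settle,window per-point settle/analysis durations, ms.
#' @param spike_threshold spike detection threshold, mV.
#' @return A list with `branches` (data frame: `I_inj`, `direction`,
#'   `spiking`, `min_V`, `max_V`, `frequency`), `equilibria` (list per grid
#'   point) and `coexistence` (`c(lo, hi)` current interval where the
#'   ascending pass is silent but the descending pass spikes; `NULL` if
#'   empty).
#' @export
continuation_diagram <- function(params, I_grid, settle = 2000, window = 1000,
                                 spike_threshold = -10) {
  stopifnot(!is.unsorted(I_grid))
  run_pass <- function(grid, init) {
    st <- init
    rows <- vector("list", length(grid))
    for (i in seq_along(grid)) {
      lc <- trace_limit_cycle(params, grid[i], st, settle = settle,
                              window = window,
                              spike_threshold = spike_threshold)
      st <- lc$final_state
      rows[[i]] <- data.frame(I_inj = grid[i], spiking = lc$exists,
                              min_V = lc$min_V, max_V = lc$max_V,
                              frequency = lc$frequency)
    }
    do.call(rbind, rows)
  }
  init_lo <- resting_state(params, I_inj = I_grid[1])
  asc <- run_pass(I_grid, init_lo)
  asc$direction <- "ascending"
  # kick the system into the spiking regime at the top of the grid
  top <- max(I_grid)
  kick <- simulate_program(
    params, current_program(c(500, 500), c(top + 3, top)),
    init = mn_state(-80), keep_trace = FALSE)
  desc <- run_pass(rev(I_grid), kick$final_state)
  desc$direction <- "descending"
  eqs <- lapply(I_grid, function(I) find_equilibria(params, I))
  both <- merge(asc[c("I_inj", "spiking")], desc[c("I_inj", "spiking")],
                by = "I_inj", suffixes = c("_asc", "_desc"))
  co <- both$I_inj[!both$spiking_asc & both$spiking_desc]
  list(branches = rbind(asc, desc), equilibria = eqs,
       coexistence = if (length(co)) range(co) else NULL)
}
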