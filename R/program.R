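#' Piecewise injected-current programs
#'
#' A `current_program` is an ordered list of segments, each holding the
#' injected current constant or ramping it linearly for a given duration.
#' Values are continuous within a segment; jumps are allowed at segment
#' boundaries (steps).
#'
#' @param durations segment durations, ms (> 0).
#' @param start_values current at the start of each segment, uA/cm2.
#' @param end_values current at the end of each segment; defaults to
#'   `start_values` (constant segments).
#' @return An object of class `current_program` with columns `t0`, `t1`,
#'   `start`, `end`, `kind`.
#' @seealso [make_ramp()], [make_step_validation()], [make_holding_ladder()]
#' @examples
#' prog <- current_program(c(1000, 500), c(0, 2))
#' program_value(prog, c(0, 1200, 1500))
#' @export
current_program <- function(durations, start_values,
                            end_values = start_values) {
  n <- length(durations)
  stopifnot(length(start_values) == n, length(end_values) == n)
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("segment durations must be positive")
  t1 <- cumsum(as.numeric(durations))
  t0 <- c(0, t1[-n])
  prog <- data.frame(
    t0 = t0, t1 = t1,
    start = as.numeric(start_values), end = as.numeric(end_values),
    kind = ifelse(start_values == end_values, "constant", "linear-ramp"),
    stringsAsFactors = FALSE
  )
  class(prog) <- c("current_program", "data.frame")
  prog
}

#' @export
print.current_program <- function(x, ...) {
  cat(sprintf("Injected-current program: %d segment(s), %.4g ms total\n",
              nrow(x), total_duration(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @rdname current_program
#' @param program a `current_program`.
#' @export
total_duration <- function(program) {
  stopifnot(inherits(program, "current_program"))
  program$t1[nrow(program)]
}

#' Evaluate a current program at given times
#'
#' @param program a `current_program`.
#' @param t times in ms, within `[0, total_duration(program)]`.
#'   At interior segment boundaries the later segment's value is returned.
#' @return Injected current, uA/cm2.
#' @export
program_value <- function(program, t) {
  stopifnot(inherits(program, "current_program"))
  if (any(t < -1e-9 | t > total_duration(program) + 1e-9))
    stop("time outside the program's span")
  idx <- findInterval(t, program$t0, rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), nrow(program))
  th <- (t - program$t0[idx]) / (program$t1[idx] - program$t0[idx])
  th <- pmin(pmax(th, 0), 1)
  program$start[idx] + th * (program$end[idx] - program$start[idx])
}

program_matrix <- function(program) {
  stopifnot(inherits(program, "current_program"))
  cbind(program$t0, program$t1, program$start, program$end)
}

#' Symmetric triangular current ramp
#'
#' Current rises linearly from 0 to `max_I` over `phase_duration` ms
#' (ascending phase) and falls back to 0 at the same rate (descending phase).
#' This is the probe used to detect hysteresis between the spiking onset
#' threshold (I_up, ascending) and offset threshold (I_down, descending).
#'
#' @param max_I ramp peak, uA/cm2 (> 0).
#' @param phase_duration duration of each phase, ms.
#' @return A `current_program` of two segments.
#' @examples
#' make_ramp(3, 5000)
#' @export
make_ramp <- function(max_I, phase_duration) {
  if (max_I <= 0) stop("max_I must be > 0")
  current_program(rep(phase_duration, 2), c(0, max_I), c(max_I, 0))
}

#' Step protocol validating bistability
#'
#' Five constant plateaus `0, I_mid, I_high, I_mid, 0`, each lasting `dwell`
#' ms. With `I_down < I_mid < I_up < I_high`, a bistable cell is silent on the
#' first `I_mid` plateau and keeps firing on the second one, having been
#' activated at `I_high` in between.
#'
#' @param I_mid intermediate current inside the suspected bistable range.
#' @param I_high current above the spiking onset threshold.
#' @param dwell plateau duration, ms.
#' @return A `current_program`. If `I_mid == I_high` the program degenerates
#'   to three levels `0, I_mid, 0`.
#' @export
make_step_validation <- function(I_mid, I_high, dwell) {
  if (I_mid > I_high) stop("I_mid must not exceed I_high")
  if (I_mid == I_high)
    return(current_program(rep(dwell, 3), c(0, I_mid, 0)))
  current_program(rep(dwell, 5), c(0, I_mid, I_high, I_mid, 0))
}

#' Holding-current ladder with test pulse and hyperpolarizing probe
#'
#' Emulates the experimental bistability assay: from each holding current, a
#' depolarizing pulse (default 2 s) is delivered; after a post-pulse
#' observation window (default 7.5 s, over which any self-sustained firing or
#' slow afterdepolarization is expressed) a brief hyperpolarizing pulse tests
#' whether the cell can be reset to the downstate, followed by a tail window.
#'
#' @param pulse_amp depolarizing pulse amplitude, uA/cm2, added on top of the
#'   holding current.
#' @param pulse_dur pulse duration, ms (default 2000).
#' @param holding_values holding currents, uA/cm2 (one program per value).
#' @param hyperpulse_amp amplitude of the hyperpolarizing probe, uA/cm2,
#'   added to holding (default -2).
#' @param hyperpulse_delay delay from pulse end to the probe, ms
#'   (default 7500).
#' @param hyperpulse_dur probe duration, ms (default 500).
#' @param pre_dur pre-pulse baseline, ms (default 2000).
#' @param tail_dur post-probe observation window, ms (default 2000).
#' @return A list of `current_program`s, one per holding value, with the
#'   holding values attached as attribute `holding` and the pulse timing as
#'   attributes `pulse_on`, `pulse_off`, `probe_on`.
#' @export
make_holding_ladder <- function(pulse_amp, pulse_dur = 2000, holding_values,
                                hyperpulse_amp = -2, hyperpulse_delay = 7500,
                                hyperpulse_dur = 500, pre_dur = 2000,
                                tail_dur = 2000) {
  if (pulse_dur <= 0) stop("pulse_dur must be > 0")
  progs <- lapply(holding_values, function(h) {
    current_program(
      c(pre_dur, pulse_dur, hyperpulse_delay, hyperpulse_dur, tail_dur),
      c(h, h + pulse_amp, h, h + hyperpulse_amp, h)
    )
  })
  attr(progs, "holding") <- holding_values
  attr(progs, "pulse_on") <- pre_dur
  attr(progs, "pulse_off") <- pre_dur + pulse_dur
  attr(progs, "probe_on") <- pre_dur + pulse_dur + hyperpulse_delay
  attr(progs, "probe_off") <- pre_dur + pulse_dur + hyperpulse_delay +
    hyperpulse_dur
  class(progs) <- "holding_ladder"
  progs
}
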