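#' Step voltage-clamp protocols
#'
#' A protocol is a tibble of piecewise-constant command-voltage segments with
#' columns `level_mV` and `duration_ms`. Segments are left-closed/right-open:
#' at a boundary the *later* segment's level applies, so each transient is
#' attributed to the level that caused it. The first segment is the holding
#' level used to initialise simulations.
#'
#' @param levels Segment command voltages (mV).
#' @param durations Segment durations (ms), all positive.
#' @return A `vc_protocol` tibble.
#' @examples
#' protocol(c(-80, 50, -80), c(20, 20, 20))
#' @export
protocol <- function(levels, durations) {
  stopifnot(length(levels) == length(durations), length(levels) >= 1,
            all(is.finite(levels)), all(is.finite(durations)),
            all(durations > 0))
  tibble::new_tibble(
    list(level_mV = as.numeric(levels), duration_ms = as.numeric(durations)),
    class = "vc_protocol"
  )
}

#' Three-segment step protocol (hold, step, return)
#'
#' @param hold Holding voltage (mV).
#' @param hold_ms Duration of the initial holding segment (ms).
#' @param step Test step voltage (mV).
#' @param step_ms Duration of the test step (ms).
#' @param tail_ms Duration of the return-to-holding tail (ms); `0` omits the
#'   tail segment.
#' @return A `vc_protocol` tibble.
#' @examples
#' step_protocol(-80, 20, 50, 20, 20)  # the model-cell stress-test step
#' @export
step_protocol <- function(hold = -80, hold_ms = 20, step = 50, step_ms = 20,
                          tail_ms = 20) {
  stopifnot(hold_ms > 0, step_ms > 0, tail_ms >= 0)
  if (tail_ms > 0) {
    protocol(c(hold, step, hold), c(hold_ms, step_ms, tail_ms))
  } else {
    protocol(c(hold, step), c(hold_ms, step_ms))
  }
}

#' Family of I-V step protocols
#'
#' One protocol per test voltage, from `v_start` to `v_end` inclusive in
#' increments of `v_inc`. The defaults reproduce the sodium-current I-V
#' family used throughout the package's bias studies: hold at -100 mV for
#' 2000 ms, then 20 ms test steps from -90 to +50 mV in 10 mV increments.
#'
#' @param hold Holding voltage (mV).
#' @param hold_ms Holding duration (ms).
#' @param v_start,v_end First and last test voltages (mV), `v_end >= v_start`.
#' @param v_inc Voltage increment (mV), positive.
#' @param step_ms Test step duration (ms).
#' @param tail_ms Optional return-to-holding tail (ms).
#' @return A named list of `vc_protocol` tibbles with attribute
#'   `test_voltages`.
#' @examples
#' length(iv_protocols(-100, 1980, -80, 60, 10, 20))  # 15 test voltages
#' @export
iv_protocols <- function(hold = -100, hold_ms = 2000, v_start = -90,
                         v_end = 50, v_inc = 10, step_ms = 20, tail_ms = 0) {
  stopifnot(v_inc > 0, v_end >= v_start)
  voltages <- seq(v_start, v_end, by = v_inc)
  out <- lapply(voltages, function(v) {
    step_protocol(hold, hold_ms, v, step_ms, tail_ms)
  })
  names(out) <- sprintf("%+.0fmV", voltages)
  attr(out, "test_voltages") <- voltages
  out
}

#' Command voltage at a time point
#'
#' Piecewise-constant lookup with the left-closed/right-open segment
#' convention: exactly at a boundary the later segment's level applies; at
#' the final end time the last level applies.
#'
#' @param protocol A `vc_protocol` tibble.
#' @param t Time points (ms) in `[0, total duration]`.
#' @return Command voltage(s) in mV.
#' @export
voltage_at <- function(protocol, t) {
  ends <- cumsum(protocol$duration_ms)
  total <- ends[length(ends)]
  if (any(t < 0 | t > total)) {
    stop("`t` must lie within [0, ", total, "] ms.", call. = FALSE)
  }
  idx <- findInterval(t, c(0, ends), rightmost.closed = TRUE,
                      left.open = FALSE)
  protocol$level_mV[pmin(idx, nrow(protocol))]
}

#' Total duration of a protocol
#' @param protocol A `vc_protocol` tibble.
#' @return Duration in ms.
#' @export
protocol_duration <- function(protocol) sum(protocol$duration_ms)
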