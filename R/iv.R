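#' Extract a current-voltage (I-V) curve from a family of traces
#'
#' For each protocol's test step, the peak is the signed extremum (largest
#' absolute value, sign preserved) of the post-processed current `Ipost`
#' within a detection window that starts a blanking interval after the step
#' onset — skipping the residual capacitive spike — and ends at the step
#' end. Time-to-peak is measured from the step onset; ties at equal extrema
#' resolve to the earliest time.
#'
#' @param traces List of `vc_trace` tibbles, one per protocol (already
#'   leak-subtracted: `ipost_nA` is used).
#' @param protocols List of `vc_protocol` tibbles matching `traces`; defaults
#'   to the protocols embedded in the traces.
#' @param blank_ms Blanking interval after step onset excluded from peak
#'   detection (ms).
#' @param step_segment Index of the test-step segment within each protocol.
#' @param direction Peak definition: `"abs"` (signed extremum of largest
#'   magnitude, the default), `"inward"` (most negative value, the standard
#'   reading for inward sodium currents — robust against residual outward
#'   capacitive transients), or `"outward"` (most positive).
#' @return A `vc_iv` tibble with columns `voltage_mV`, `peak_current_nA`,
#'   `time_to_peak_ms`, sorted by voltage.
#' @export
compute_iv <- function(traces, protocols = NULL, blank_ms = 0.2,
                       step_segment = 2L,
                       direction = c("abs", "inward", "outward")) {
  direction <- match.arg(direction)
  if (inherits(traces, "vc_trace")) traces <- list(traces)
  protocols <- protocols %||% lapply(traces, attr, "protocol")
  stopifnot(length(traces) == length(protocols))
  rows <- purrr::map2(traces, protocols, function(tr, pr) {
    stopifnot(inherits(pr, "vc_protocol"), nrow(pr) >= step_segment)
    on <- c(0, cumsum(pr$duration_ms))[step_segment]
    off <- on + pr$duration_ms[step_segment]
    sel <- tr$time_ms >= on + blank_ms & tr$time_ms < off
    if (!any(sel)) {
      stop("Empty peak-detection window: blanking interval exceeds the ",
           "test step duration.", call. = FALSE)
    }
    ii <- tr$ipost_nA[sel]
    tt <- tr$time_ms[sel]
    k <- switch(direction,            # first index at ties -> earliest time
                abs = which.max(abs(ii)),
                inward = which.min(ii),
                outward = which.max(ii))
    tibble::tibble(voltage_mV = pr$level_mV[step_segment],
                   peak_current_nA = ii[k],
                   time_to_peak_ms = tt[k] - on)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$voltage_mV)
  class(out) <- c("vc_iv", class(out))
  out
}

#' Pointwise mean and SEM of I-V curves
#'
#' @param curves List of `vc_iv` tibbles sharing the same voltage grid.
#' @return A `vc_iv` tibble with `peak_current_nA` the pointwise mean and an
#'   added `sem` column (`sd/sqrt(n)`), plus `n`.
#' @export
average_iv <- function(curves) {
  stopifnot(length(curves) >= 2)
  grids <- lapply(curves, function(cv) cv$voltage_mV)
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    stop("All I-V curves must share the same voltage grid.", call. = FALSE)
  }
  peaks <- vapply(curves, function(cv) cv$peak_current_nA,
                  numeric(nrow(curves[[1]])))
  out <- tibble::tibble(
    voltage_mV = grids[[1]],
    peak_current_nA = rowMeans(peaks),
    sem = apply(peaks, 1, stats::sd) / sqrt(length(curves)),
    n = length(curves)
  )
  class(out) <- c("vc_iv", class(out))
  out
}

#' Peak of an I-V curve
#'
#' @param iv A `vc_iv` tibble.
#' @return A one-row tibble with the voltage and (signed) current at the
#'   curve's largest-magnitude point; ties resolve to the lowest voltage.
#' @export
iv_peak <- function(iv) {
  k <- which.max(abs(iv$peak_current_nA))
  tibble::tibble(voltage_mV = iv$voltage_mV[k],
                 peak_current_nA = iv$peak_current_nA[k])
}

#' Simulate an I-V protocol family and extract the curve
#'
#' Convenience wrapper: simulate each protocol of the family with
#' [simulate_clamp()] (or [simulate_ideal()] when `ideal = TRUE`), then
#' apply [compute_iv()].
#'
#' @inheritParams simulate_clamp
#' @param protocols A protocol family from [iv_protocols()].
#' @param ideal Simulate without artefacts (ionic model only)?
#' @param blank_ms Peak-detection blanking interval (ms).
#' @param direction Peak definition, see [compute_iv()].
#' @param ... Passed on to the simulator.
#' @return A `vc_iv` tibble.
#' @export
simulate_iv <- function(settings, cell, model, protocols, ideal = FALSE,
                        dt_out = 0.01, dt_hold = 5, blank_ms = 0.2,
                        direction = "abs", ...) {
  traces <- lapply(protocols, function(p) {
    if (ideal) {
      simulate_ideal(model, p, dt_out = dt_out, dt_hold = dt_hold)
    } else {
      simulate_clamp(settings, cell, model, p, dt_out = dt_out,
                     dt_hold = dt_hold, ...)
    }
  })
  compute_iv(traces, protocols, blank_ms = blank_ms, direction = direction)
}
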