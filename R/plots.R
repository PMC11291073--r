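#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated or recorded trace
#'
#' Two stacked panels: command and membrane voltage on top, measured
#' (`Iout`) and post-processed (`Ipost`) current below.
#'
#' @param object A `vc_trace` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vc_trace <- function(object, ...) {
  volt <- tidyr::pivot_longer(
    object[c("time_ms", "vcmd_mV", "vm_mV")],
    -"time_ms", names_to = "signal", values_to = "value")
  volt$panel <- "voltage (mV)"
  curr <- tidyr::pivot_longer(
    object[c("time_ms", "iout_nA", "ipost_nA")],
    -"time_ms", names_to = "signal", values_to = "value")
  curr$panel <- "current (nA)"
  df <- rbind(volt, curr)
  df$panel <- factor(df$panel, levels = c("voltage (mV)", "current (nA)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$value,
                                   colour = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y",
                        switch = "y") +
    ggplot2::labs(x = "time (ms)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.placement = "outside")
}

#' Plot an I-V curve
#'
#' @param object A `vc_iv` tibble; if it carries a `sem` column, error bars
#'   are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vc_iv <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$voltage_mV,
                                            .data$peak_current_nA)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "test voltage (mV)", y = "peak current (nA)") +
    ggplot2::theme_minimal()
  if ("sem" %in% names(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$peak_current_nA - .data$sem,
                   ymax = .data$peak_current_nA + .data$sem),
      width = 2)
  }
  p
}

#' Plot a compensation sweep as overlaid current traces
#'
#' @param object A tibble from [compensation_sweep()].
#' @param signal Trace column to overlay (default the measured current).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vc_sweep <- function(object, signal = "iout_nA", ...) {
  df <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
    tr <- object$trace[[i]]
    tibble::tibble(
      time_ms = tr$time_ms, value = tr[[signal]],
      setting = sprintf("aR=%.0f%% aP=%.0f%%", 100 * object$alpha_R[i],
                        100 * object$alpha_P[i]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$value,
                                   colour = .data$setting)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (ms)", y = signal, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the averaging-bias study
#'
#' Individual compensated I-V curves in grey, their mean with SEM error
#' bars in blue, and the artefact-free reference in red.
#'
#' @param object A `vc_averaging_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vc_averaging_study <- function(object, ...) {
  ind <- dplyr::bind_rows(lapply(seq_along(object$curves), function(i) {
    dplyr::mutate(object$curves[[i]], cell = i)
  }))
  ggplot2::ggplot(mapping = ggplot2::aes(.data$voltage_mV,
                                         .data$peak_current_nA)) +
    ggplot2::geom_line(data = ind, ggplot2::aes(group = .data$cell),
                       colour = "grey70", alpha = 0.5) +
    ggplot2::geom_line(data = object$mean_iv, colour = "blue") +
    ggplot2::geom_errorbar(
      data = object$mean_iv,
      ggplot2::aes(ymin = .data$peak_current_nA - .data$sem,
                   ymax = .data$peak_current_nA + .data$sem),
      colour = "blue", width = 2) +
    ggplot2::geom_line(data = object$ideal_iv, colour = "red") +
    ggplot2::labs(x = "test voltage (mV)", y = "peak current (nA)") +
    ggplot2::theme_minimal()
}

#' Plot the mutant/drug study
#'
#' Mean observed I-V per arm (solid, with SEM) and the ideal-clamp curves
#' (dashed).
#'
#' @param object A `vc_mutant_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vc_mutant_study <- function(object, ...) {
  obs <- dplyr::bind_rows(lapply(names(object$mean_ivs), function(a) {
    dplyr::mutate(object$mean_ivs[[a]], arm = a)
  }))
  ide <- dplyr::bind_rows(lapply(names(object$ideal_ivs), function(a) {
    dplyr::mutate(object$ideal_ivs[[a]], arm = a)
  }))
  ggplot2::ggplot(mapping = ggplot2::aes(.data$voltage_mV,
                                         .data$peak_current_nA,
                                         colour = .data$arm)) +
    ggplot2::geom_line(data = obs) +
    ggplot2::geom_errorbar(
      data = obs,
      ggplot2::aes(ymin = .data$peak_current_nA - .data$sem,
                   ymax = .data$peak_current_nA + .data$sem),
      width = 2) +
    ggplot2::geom_line(data = ide, linetype = "dashed") +
    ggplot2::labs(x = "test voltage (mV)", y = "peak current (nA)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
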