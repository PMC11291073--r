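#' Amplifier settings for a voltage-clamp experiment
#'
#' Bundles the machine-side quantities of the voltage-clamp artefact model:
#' the requested compensation levels, the amplifier's *estimates* of the cell
#' parameters (marked with a star in the circuit analysis), and the amplifier
#' time constants.
#'
#' @param alpha_R Series-resistance compensation level, a fraction in `[0, 1)`.
#' @param alpha_P Supercharging ("prediction") compensation level, a fraction
#'   in `[0, 0.999]`. Values of 1 and above are rejected because the
#'   supercharging time constant `(1 - alpha_P) * Rs_est * Cm_est` would be
#'   zero or negative.
#' @param Rs_est Machine estimate of the series resistance (MOhm).
#' @param Cm_est Machine estimate of the membrane capacitance (pF).
#' @param Cp_est Machine estimate of the pipette (parasitic) capacitance (pF).
#' @param gleak_est Leak conductance estimate used for leak subtraction (uS).
#' @param Eleak_est Leak reversal voltage estimate (mV).
#' @param tau_sum Response time of the summing amplifier (ms). Default 1 us.
#' @param tau_clamp Voltage-clamp time constant (ms). Default 0.8 us.
#' @param tau_z Transconductor (output filter) time constant, the product of
#'   feedback resistance and capacitance (ms). Default 7.5 us.
#'
#' @return An object of class `vc_amplifier` (a named list).
#' @examples
#' amplifier_settings(alpha_R = 0.8, alpha_P = 0.8, Rs_est = 10, Cm_est = 20)
#' @export
amplifier_settings <- function(alpha_R = 0, alpha_P = 0,
                               Rs_est = 10, Cm_est = 20, Cp_est = 4,
                               gleak_est = 0, Eleak_est = 0,
                               tau_sum = 1e-3, tau_clamp = 8e-4,
                               tau_z = 7.5e-3) {
  stopifnot(
    is.numeric(alpha_R), length(alpha_R) == 1, is.finite(alpha_R),
    is.numeric(alpha_P), length(alpha_P) == 1, is.finite(alpha_P)
  )
  if (alpha_R < 0 || alpha_R >= 1) {
    stop("`alpha_R` must be a fraction in [0, 1).", call. = FALSE)
  }
  if (alpha_P < 0 || alpha_P > 0.999) {
    stop("`alpha_P` must be a fraction in [0, 0.999]: the supercharging ",
         "time constant (1 - alpha_P) * Rs_est * Cm_est must stay positive.",
         call. = FALSE)
  }
  check_positive(c(Rs_est = Rs_est, Cm_est = Cm_est,
                   tau_sum = tau_sum, tau_clamp = tau_clamp, tau_z = tau_z))
  check_nonnegative(c(Cp_est = Cp_est, gleak_est = gleak_est))
  stopifnot(is.finite(Eleak_est))
  structure(
    lapply(list(alpha_R = alpha_R, alpha_P = alpha_P,
                Rs_est = Rs_est, Cm_est = Cm_est, Cp_est = Cp_est,
                gleak_est = gleak_est, Eleak_est = Eleak_est,
                tau_sum = tau_sum, tau_clamp = tau_clamp, tau_z = tau_z),
           function(x) unname(as.numeric(x))),
    class = "vc_amplifier"
  )
}

#' Physical properties of the patched cell and pipette
#'
#' The true (as opposed to machine-estimated) parameters of the cell-pipette
#' system: series resistance, membrane and pipette capacitance, seal leak, and
#' the residual voltage offset left after the amplifier's offset compensation.
#'
#' @param Rs Series (access) resistance between pipette electrode and cell
#'   interior (MOhm).
#' @param Cm Membrane capacitance (pF).
#' @param Cp Parasitic/pipette capacitance (pF).
#' @param gleak Seal leak conductance (uS); the seal resistance is `1/gleak`.
#' @param Eleak Leak reversal voltage (mV).
#' @param Voff Residual voltage offset (mV). Only the *residual* offset (true
#'   offset minus the amplifier's correction) enters the model, so it is
#'   stored directly rather than as two separate quantities.
#'
#' @return An object of class `vc_cell` (a named list).
#' @examples
#' cell_properties(Rs = 10, Cm = 20, Cp = 4, gleak = 0.001)
#' @export
cell_properties <- function(Rs = 10, Cm = 20, Cp = 4,
                            gleak = 0, Eleak = 0, Voff = 0) {
  check_positive(c(Rs = Rs, Cm = Cm))
  check_nonnegative(c(Cp = Cp, gleak = gleak))
  stopifnot(is.finite(Eleak), is.finite(Voff))
  structure(
    lapply(list(Rs = Rs, Cm = Cm, Cp = Cp,
                gleak = gleak, Eleak = Eleak, Voff = Voff),
           function(x) unname(as.numeric(x))),
    class = "vc_cell"
  )
}

#' @export
print.vc_amplifier <- function(x, ...) {
  cat("<voltage-clamp amplifier settings>\n")
  cat(sprintf("  compensation: alpha_R = %.0f%%, alpha_P = %.0f%%\n",
              100 * x$alpha_R, 100 * x$alpha_P))
  cat(sprintf("  estimates:    Rs* = %g MOhm, Cm* = %g pF, Cp* = %g pF\n",
              x$Rs_est, x$Cm_est, x$Cp_est))
  cat(sprintf("  leak subtr.:  gleak* = %g uS, Eleak* = %g mV\n",
              x$gleak_est, x$Eleak_est))
  cat(sprintf("  time consts:  tau_sum = %g us, tau_clamp = %g us, tau_z = %g us\n",
              1e3 * x$tau_sum, 1e3 * x$tau_clamp, 1e3 * x$tau_z))
  invisible(x)
}

#' @export
print.vc_cell <- function(x, ...) {
  cat("<cell + pipette properties>\n")
  cat(sprintf("  Rs = %g MOhm, Cm = %g pF, Cp = %g pF\n", x$Rs, x$Cm, x$Cp))
  cat(sprintf("  gleak = %g uS (Rseal = %s), Eleak = %g mV, Voff = %g mV\n",
              x$gleak,
              if (x$gleak > 0) sprintf("%g MOhm", 1 / x$gleak) else "Inf",
              x$Eleak, x$Voff))
  invisible(x)
}

check_positive <- function(x) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    stop(sprintf("%s must be positive and finite.",
                 paste0("`", names(x)[bad], "`", collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x) {
  bad <- !is.finite(x) | x < 0
  if (any(bad)) {
    stop(sprintf("%s must be non-negative and finite.",
                 paste0("`", names(x)[bad], "`", collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# pF -> nF, the package's internal capacitance unit (MOhm * nF = ms).
pf_to_nf <- function(x) x * 1e-3
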