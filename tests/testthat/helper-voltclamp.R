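# Shared fixtures, built in code.

# Model-cell rig: explicit series resistor/capacitor values of the bench
# setup, with perfect machine estimates.
rig_settings <- function(alpha_R = 0, alpha_P = 0, ...) {
  amplifier_settings(alpha_R = alpha_R, alpha_P = alpha_P,
                     Rs_est = 30, Cm_est = 22, Cp_est = 4.7, ...)
}

rig_cell <- function(Rs = 30, Cm = 22, Cp = 4.7, ...) {
  cell_properties(Rs = Rs, Cm = Cm, Cp = Cp, ...)
}

# The large-step stress-test protocol: hold -80, step +50 for 20 ms, return.
rig_protocol <- function() step_protocol(-80, 20, 50, 20, 20)

# A typical perforated-patch sodium-current recording condition.
ina_settings <- function(alpha_R = 0, alpha_P = 0, ...) {
  amplifier_settings(alpha_R = alpha_R, alpha_P = alpha_P,
                     Rs_est = 10, Cm_est = 30, Cp_est = 4, ...)
}

ina_cell <- function(Rs = 10, Cm = 30, Cp = 4, ...) {
  cell_properties(Rs = Rs, Cm = Cm, Cp = Cp, ...)
}

# Maximum relative discrepancy between two traces, scaled per column by the
# reference's dynamic range.
trace_rel_error <- function(a, b, cols = c("vm_mV", "vp_mV", "vclamp_mV",
                                           "vest_mV", "iout_nA")) {
  max(vapply(cols, function(cl) {
    max(abs(a[[cl]] - b[[cl]])) / max(abs(b[[cl]]), 1e-12)
  }, numeric(1)))
}

# Independent R implementation of the no-supercharging (prior-generation)
# clamp model: the supercharging feed-forward is struck from the effective
# command and the estimated membrane voltage relaxes with Rs* Cm*. Written
# directly from the circuit relations, not via artefact_rhs().
reduced_rhs <- function(t, y, parms) {
  with(parms, {
    Vm <- y[1]; Vp <- y[2]; Vclamp <- y[3]; Vest <- y[4]; Iout <- y[5]
    dVest <- (Vcmd - Vest) / (Rs_est * Cm_est)
    Vcmd_p <- Vcmd + Rs_est * alpha_R * Iout
    dVclamp <- (Vcmd_p - Vclamp) / tau_sum
    dVp <- (Vclamp - Vp) / tau_clamp
    Iion <- ion_current(Vm, y[-(1:5)])
    Ileak <- gleak * (Vm - Eleak)
    dVm <- (Vp + Voff - Vm) / (Rs * Cm) - (Iion + Ileak) / Cm
    Iin <- Iion + Ileak + Cp * dVp - Cp_est * dVclamp +
      Cm * dVm - Cm_est * dVest
    dion <- ion_deriv(Vm, y[-(1:5)], dVm)
    list(c(dVm, dVp, dVclamp, dVest, (Iin - Iout) / tau_z, dion))
  })
}

# Integrate the reduced model over a protocol from a supplied initial state.
simulate_reduced <- function(settings, cell, model, protocol, y0,
                             dt_out = 0.01) {
  stopifnot(settings$alpha_P == 0)
  if (inherits(model, "vc_model_cell")) {
    ion_current <- function(Vm, s) s[1] + Vm / model$Rm
    ion_deriv <- function(Vm, s, dVm) {
      ck <- model$Ck * 1e-3
      (ck * dVm - s[1]) / (model$Rk * ck)
    }
  } else {
    ion_current <- function(Vm, s) ionic_current(model, Vm, s)
    ion_deriv <- function(Vm, s, dVm) ionic_rhs(model, Vm, s, dVm)$deriv
  }
  parms <- list(
    alpha_R = settings$alpha_R, Rs_est = settings$Rs_est,
    Cm_est = settings$Cm_est * 1e-3, Cp_est = settings$Cp_est * 1e-3,
    tau_sum = settings$tau_sum, tau_clamp = settings$tau_clamp,
    tau_z = settings$tau_z, Rs = cell$Rs, Cm = cell$Cm * 1e-3,
    Cp = cell$Cp * 1e-3, gleak = cell$gleak, Eleak = cell$Eleak,
    Voff = cell$Voff, Vcmd = NA_real_,
    ion_current = ion_current, ion_deriv = ion_deriv
  )
  y <- y0
  pieces <- list()
  t0 <- 0
  for (i in seq_len(nrow(protocol))) {
    parms$Vcmd <- protocol$level_mV[i]
    tt <- seq(0, protocol$duration_ms[i], by = dt_out)
    if (tt[length(tt)] < protocol$duration_ms[i]) {
      tt <- c(tt, protocol$duration_ms[i])
    }
    sol <- deSolve::ode(y, tt, reduced_rhs, parms, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10, maxsteps = 50000)
    y <- sol[nrow(sol), -1]
    keep <- if (i < nrow(protocol)) seq_len(nrow(sol) - 1) else
      seq_len(nrow(sol))
    pieces[[i]] <- cbind(time_ms = t0 + sol[keep, 1],
                        sol[keep, -1, drop = FALSE])
    t0 <- t0 + protocol$duration_ms[i]
  }
  do.call(rbind, pieces)
}

# Single-exponential time constant from a log-linear fit of |x - x_inf|.
fit_exp_tau <- function(t, x, x_inf = 0) {
  r <- abs(x - x_inf)
  keep <- r > max(r) * 1e-6
  -1 / unname(stats::coef(stats::lm(log(r[keep]) ~ t[keep]))[2])
}
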