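#' Affine state-space form of the model-cell clamp system
#'
#' With the electrical model cell attached, the entire coupled
#' cell-amplifier system is linear time-invariant within each
#' constant-command segment: `dx/dt = A x + b Vcmd + c`, with state
#' `x = (Vm, Vp, Vclamp, Vest, Iout, Ik)`. This function assembles `A`, `b`
#' and `c` directly from the circuit equations, term by term, independently
#' of the simulator's right-hand side — it is the package's validation
#' oracle for the numerical integrator.
#'
#' @inheritParams artefact_rhs
#' @param model A [model_cell()].
#' @return A list with matrix `A` (6x6), vectors `b` and `c0` (length 6),
#'   and the state names.
#' @export
model_cell_system <- function(settings, cell, model = model_cell()) {
  stopifnot(inherits(model, "vc_model_cell"))
  aR <- settings$alpha_R; aP <- settings$alpha_P
  Rse <- settings$Rs_est
  cme <- pf_to_nf(settings$Cm_est); cpe <- pf_to_nf(settings$Cp_est)
  tsum <- settings$tau_sum; tclamp <- settings$tau_clamp; tz <- settings$tau_z
  Rs <- cell$Rs; cm <- pf_to_nf(cell$Cm); cp <- pf_to_nf(cell$Cp)
  gl <- cell$gleak; El <- cell$Eleak; Voff <- cell$Voff
  Rk <- model$Rk; ck <- pf_to_nf(model$Ck); Rm <- model$Rm

  nm <- c("Vm", "Vp", "Vclamp", "Vest", "Iout", "Ik")
  A <- matrix(0, 6, 6, dimnames = list(nm, nm))
  b <- stats::setNames(numeric(6), nm)
  c0 <- stats::setNames(numeric(6), nm)

  # supercharging estimate: dVest = (Vcmd - Vest) / ((1-aP) Rs* Cm*)
  k5 <- (1 - aP) * Rse * cme
  A["Vest", "Vest"] <- -1 / k5
  b["Vest"] <- 1 / k5

  # effective command: Vcmd' = (1+q) Vcmd - q Vest + Rs* aR Iout,
  # q = aP/(1-aP) (substituting dVest/dt from the line above)
  q <- aP / (1 - aP)

  # summing amplifier: dVclamp = (Vcmd' - Vclamp) / tau_sum
  A["Vclamp", "Vclamp"] <- -1 / tsum
  A["Vclamp", "Vest"] <- -q / tsum
  A["Vclamp", "Iout"] <- Rse * aR / tsum
  b["Vclamp"] <- (1 + q) / tsum

  # clamp lag: dVp = (Vclamp - Vp) / tau_clamp
  A["Vp", "Vp"] <- -1 / tclamp
  A["Vp", "Vclamp"] <- 1 / tclamp

  # membrane: dVm = (Vp + Voff - Vm)/(Rs Cm) - (Ik + Vm/Rm + gl (Vm-El))/Cm
  A["Vm", "Vm"] <- -1 / (Rs * cm) - (1 / Rm + gl) / cm
  A["Vm", "Vp"] <- 1 / (Rs * cm)
  A["Vm", "Ik"] <- -1 / cm
  c0["Vm"] <- Voff / (Rs * cm) + gl * El / cm

  # dynamic branch: dIk = (Ck dVm - Ik)/(Rk Ck) = dVm/Rk - Ik/(Rk Ck)
  A["Ik", ] <- A["Vm", ] / Rk
  A["Ik", "Ik"] <- A["Ik", "Ik"] - 1 / (Rk * ck)
  b["Ik"] <- b["Vm"] / Rk
  c0["Ik"] <- c0["Vm"] / Rk

  # measured current: tz dIout = Iion + Ileak + Cp dVp - Cp* dVclamp
  #                              + Cm dVm - Cm* dVest - Iout
  rowI <- (cp * A["Vp", ] - cpe * A["Vclamp", ] + cm * A["Vm", ] -
             cme * A["Vest", ]) / tz
  rowI["Vm"] <- rowI["Vm"] + (1 / Rm + gl) / tz
  rowI["Ik"] <- rowI["Ik"] + 1 / tz
  rowI["Iout"] <- rowI["Iout"] - 1 / tz
  A["Iout", ] <- rowI
  b["Iout"] <- (cp * b["Vp"] - cpe * b["Vclamp"] + cm * b["Vm"] -
                  cme * b["Vest"]) / tz
  c0["Iout"] <- (cp * c0["Vp"] - cpe * c0["Vclamp"] + cm * c0["Vm"] -
                   cme * c0["Vest"] - gl * El) / tz

  list(A = A, b = b, c0 = c0, state_names = nm)
}

#' Closed-form simulation of the model-cell clamp system
#'
#' Solves the affine system from [model_cell_system()] exactly on each
#' protocol segment via the eigendecomposition of `A`:
#' `x(t) = x_inf + V exp(D t) V^{-1} (x0 - x_inf)` with
#' `x_inf = -A^{-1} (b Vcmd + c)`. Complex eigenvalues (the ringing seen at
#' high compensation) are handled in complex arithmetic; the result is real
#' to rounding error and the imaginary part is dropped. This closed form is
#' the reference the stiff numerical integrator is validated against.
#'
#' @inheritParams simulate_clamp
#' @param model A [model_cell()].
#' @return A `vc_trace` tibble, sampled like [simulate_clamp()].
#' @export
simulate_model_cell_exact <- function(settings, cell, model, protocol,
                                      dt_out = 0.01, dt_hold = NULL) {
  stopifnot(inherits(model, "vc_model_cell"),
            inherits(protocol, "vc_protocol"))
  sys <- model_cell_system(settings, cell, model)
  eg <- eigen(sys$A)
  V <- eg$vectors
  Vinv <- solve(V)

  x <- model_cell_equilibrium(sys, protocol$level_mV[1])
  pieces <- vector("list", nrow(protocol))
  t0 <- 0
  for (i in seq_len(nrow(protocol))) {
    lev <- protocol$level_mV[i]
    dur <- protocol$duration_ms[i]
    dt <- if (i == 1 && !is.null(dt_hold)) dt_hold else dt_out
    tt <- segment_times(dur, dt)
    xinf <- model_cell_equilibrium(sys, lev)
    w <- Vinv %*% (x - xinf)
    # states x time matrix: xinf + V diag(exp(lambda t)) w, vectorised in t
    ew <- exp(outer(eg$values, tt)) * as.vector(w)
    xs <- Re(V %*% ew) + xinf
    x <- xs[, ncol(xs)]
    keep <- if (i < nrow(protocol)) seq_len(length(tt) - 1) else seq_along(tt)
    pieces[[i]] <- cbind(time_ms = t0 + tt[keep], vcmd_mV = lev,
                         t(xs[, keep, drop = FALSE]))
    t0 <- t0 + dur
  }
  m <- do.call(rbind, pieces)
  colnames(m) <- c("time_ms", "vcmd_mV", sys$state_names)
  df <- tibble::tibble(
    time_ms = m[, "time_ms"], vcmd_mV = m[, "vcmd_mV"],
    vm_mV = m[, "Vm"], vp_mV = m[, "Vp"], vclamp_mV = m[, "Vclamp"],
    vest_mV = m[, "Vest"],
    iion_nA = m[, "Ik"] + m[, "Vm"] / model$Rm,
    iout_nA = m[, "Iout"],
    ipost_nA = m[, "Iout"] -
      settings$gleak_est * (m[, "vcmd_mV"] - settings$Eleak_est)
  )
  new_trace(df, settings, cell, model, protocol)
}

#' Equilibrium of the affine model-cell system at a command voltage
#'
#' @param sys Output of [model_cell_system()].
#' @param Vcmd Command voltage (mV).
#' @return Named equilibrium state vector solving `A x + b Vcmd + c = 0`.
#' @export
model_cell_equilibrium <- function(sys, Vcmd) {
  x <- solve(sys$A, -(sys$b * Vcmd + sys$c0))
  stats::setNames(as.vector(x), sys$state_names)
}
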