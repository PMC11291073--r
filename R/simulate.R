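#' @keywords internal
"_PACKAGE"

#' @useDynLib voltclamp
#' @importFrom rlang .data
#' @import tibble
NULL

# Parameter vector in the layout expected by the compiled derivatives
# (src/artefact.c); keep the two in lock-step.
.vc_parms <- function(settings, cell, model, Vcmd) {
  stopifnot(inherits(settings, "vc_amplifier"), inherits(cell, "vc_cell"),
            inherits(model, "vc_ionic_model"))
  p <- numeric(34)
  p[1:8] <- c(settings$alpha_R, settings$alpha_P, settings$Rs_est,
              pf_to_nf(settings$Cm_est), pf_to_nf(settings$Cp_est),
              settings$tau_sum, settings$tau_clamp, settings$tau_z)
  p[9:15] <- c(cell$Rs, pf_to_nf(cell$Cm), pf_to_nf(cell$Cp),
               cell$gleak, cell$Eleak, cell$Voff, Vcmd)
  if (inherits(model, "vc_model_cell")) {
    p[16] <- 0
    p[17:19] <- c(model$Rk, pf_to_nf(model$Ck), model$Rm)
  } else if (inherits(model, "vc_hh_ina")) {
    p[16] <- 1
    p[17:22] <- c(model$g_max, model$E_Na, model$act_vhalf, model$act_slope,
                  model$inact_vhalf, model$inact_slope)
    p[23:26] <- model$tau_m
    p[27:30] <- model$tau_h
    p[31:34] <- model$tau_j
  } else if (inherits(model, "vc_null_model")) {
    p[16] <- 2
  } else {
    stop("Compiled integration supports the built-in ionic models; ",
         "plug-in models are integrated through `artefact_rhs()`.",
         call. = FALSE)
  }
  p
}

.vc_compiled <- function(model) {
  inherits(model, c("vc_model_cell", "vc_hh_ina", "vc_null_model"))
}

#' Right-hand side of the coupled cell-amplifier model
#'
#' Evaluates the time derivatives of the full voltage-clamp artefact model:
#' membrane voltage `Vm`, pipette voltage `Vp`, clamp drive `Vclamp`,
#' supercharging estimate `Vest`, filtered output current `Iout`, and the
#' attached ionic model's states. This is the reference R implementation of
#' the equations; production simulation uses an equivalent compiled version.
#'
#' The pathway is: the supercharging estimate relaxes towards the command
#' with time constant `(1 - alpha_P) * Rs_est * Cm_est`; the effective
#' command `Vcmd' = Vcmd + Rs_est * (alpha_R * Iout + alpha_P * Cm_est *
#' dVest/dt)` adds the series-resistance correction and the supercharging
#' overshoot; `Vclamp` and `Vp` follow through the summing-amplifier and
#' clamp lags; the membrane charges through `Rs` against the ionic and leak
#' currents; the measured current is the physical pipette current minus the
#' machine's capacitance-compensation estimates, low-pass filtered with
#' `tau_z`.
#'
#' @param state Named state vector `(Vm, Vp, Vclamp, Vest, Iout, <ionic>)`,
#'   e.g. from [steady_state_init()].
#' @param t Time (ms); the built-in models are autonomous.
#' @param settings [amplifier_settings()].
#' @param cell [cell_properties()].
#' @param model An ionic model object.
#' @param Vcmd Command voltage at `t` (mV).
#' @return A list with `deriv` (named derivative vector, same layout as
#'   `state`), `Iion`, `Iin` (nA) and `Vcmd_prime` (mV).
#' @export
artefact_rhs <- function(state, t, settings, cell, model, Vcmd) {
  if (settings$alpha_P >= 1) {
    stop("alpha_P must be < 1 (supercharging time constant would vanish).",
         call. = FALSE)
  }
  if (any(!is.finite(state))) {
    stop("Non-finite state passed to artefact_rhs().", call. = FALSE)
  }
  Vm <- state[[1]]; Vp <- state[[2]]; Vclamp <- state[[3]]
  Vest <- state[[4]]; Iout <- state[[5]]
  ionic <- state[-(1:5)]

  cm_e <- pf_to_nf(settings$Cm_est); cp_e <- pf_to_nf(settings$Cp_est)
  cm <- pf_to_nf(cell$Cm); cp <- pf_to_nf(cell$Cp)

  dVest <- (Vcmd - Vest) / ((1 - settings$alpha_P) * settings$Rs_est * cm_e)
  Vcmd_prime <- Vcmd + settings$Rs_est *
    (settings$alpha_R * Iout + settings$alpha_P * cm_e * dVest)
  dVclamp <- (Vcmd_prime - Vclamp) / settings$tau_sum
  dVp <- (Vclamp - Vp) / settings$tau_clamp

  Ileak <- cell$gleak * (Vm - cell$Eleak)
  Iion <- ionic_current(model, Vm, ionic, t)
  dVm <- (Vp + cell$Voff - Vm) / (cell$Rs * cm) - (Iion + Ileak) / cm

  ion <- ionic_rhs(model, Vm, ionic, dVm_dt = dVm, t = t)
  Iin <- Iion + Ileak + cp * dVp - cp_e * dVclamp + cm * dVm - cm_e * dVest
  dIout <- (Iin - Iout) / settings$tau_z

  deriv <- c(Vm = dVm, Vp = dVp, Vclamp = dVclamp, Vest = dVest,
             Iout = dIout, ion$deriv)
  list(deriv = deriv, Iion = Iion, Iin = Iin, Vcmd_prime = Vcmd_prime)
}

#' Steady state of the coupled system at a holding voltage
#'
#' Finds the state at which every time derivative of the coupled
#' cell-amplifier system vanishes for a constant command `V_hold`. At
#' equilibrium all capacitive currents are zero and the amplifier chain is
#' algebraic, so the problem reduces to a scalar root-find in `Vm`
#' balancing the series-resistance voltage drop against the total membrane
#' current (with the series-resistance compensation feedback included).
#' Used to initialise every simulation so that pre-step transients reflect
#' only the protocol.
#'
#' @inheritParams artefact_rhs
#' @param V_hold Holding command voltage (mV).
#' @param tol Maximum permitted residual derivative norm (simulation units).
#' @return Named state vector `(Vm, Vp, Vclamp, Vest, Iout, <ionic>)` with
#'   attribute `residual` (the infinity norm of the right-hand side).
#' @examples
#' steady_state_init(amplifier_settings(), cell_properties(), model_cell(), -80)
#' @export
steady_state_init <- function(settings, cell, model, V_hold, tol = 1e-8) {
  itot <- function(Vm) {
    equilibrium_current(model, Vm) + cell$gleak * (Vm - cell$Eleak)
  }
  f <- function(Vm) {
    (V_hold + settings$Rs_est * settings$alpha_R * itot(Vm) +
       cell$Voff - Vm) / cell$Rs - itot(Vm)
  }
  grid <- sort(unique(c(seq(-160, 80, by = 0.5),
                        seq(V_hold - 20, V_hold + 20, by = 0.1))))
  fv <- f(grid)
  sgn <- sign(fv)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & is.finite(fv[-1]))
  if (length(cross) == 0) {
    stop("steady_state_init(): no equilibrium membrane voltage found in ",
         "[-160, 80] mV (residual norm ", format(min(abs(fv))), ").",
         call. = FALSE)
  }
  mids <- (grid[cross] + grid[cross + 1]) / 2
  k <- cross[which.min(abs(mids - (V_hold + cell$Voff)))]
  Vm <- stats::uniroot(f, c(grid[k], grid[k + 1]), tol = 1e-13)$root
  # Newton polish: at small Rs the residual norm amplifies any root error
  # by 1/(Rs*Cm), so drive f(Vm) down to rounding level
  for (it in 1:5) {
    fv1 <- f(Vm)
    if (abs(fv1) < 1e-12 * max(1, abs(Vm)) / cell$Rs) break
    h <- 1e-7 * max(1, abs(Vm))
    dfv <- (f(Vm + h) - f(Vm - h)) / (2 * h)
    if (!is.finite(dfv) || dfv == 0) break
    Vm <- Vm - fv1 / dfv
  }

  I <- itot(Vm)
  Vp <- V_hold + settings$Rs_est * settings$alpha_R * I
  state <- c(Vm = Vm, Vp = Vp, Vclamp = Vp, Vest = V_hold, Iout = I,
             ionic_steady_states(model, Vm))
  # consistency pass: absorb the rounding-level membrane imbalance into
  # Iout (the filter equation then holds exactly at the returned state)
  r1 <- artefact_rhs(state, 0, settings, cell, model, V_hold)$deriv
  state2 <- state
  state2[["Iout"]] <- state[["Iout"]] + settings$tau_z * r1[["Iout"]]
  r2 <- artefact_rhs(state2, 0, settings, cell, model, V_hold)$deriv
  if (max(abs(r2)) < max(abs(r1))) {
    state <- state2
    r1 <- r2
  }
  res <- max(abs(r1))
  # the equilibrium voltage cannot be resolved below double rounding, so
  # the attainable residual scales with the fastest rate in the system
  rate <- max(1 / (cell$Rs * pf_to_nf(cell$Cm)),
              1 / ((1 - settings$alpha_P) * settings$Rs_est *
                     pf_to_nf(settings$Cm_est)),
              1 / settings$tau_z, 1 / settings$tau_sum,
              1 / settings$tau_clamp)
  tol_eff <- max(tol, 100 * .Machine$double.eps *
                   max(100, abs(V_hold)) * rate)
  if (!is.finite(res) || res > tol_eff) {
    stop("steady_state_init() failed to converge: residual norm ",
         format(res), " exceeds tolerance ", format(tol_eff), ".",
         call. = FALSE)
  }
  attr(state, "residual") <- res
  state
}

# Ionic current with states at their equilibrium for each voltage;
# vectorised over Vm for the built-in models.
equilibrium_current <- function(model, Vm) {
  if (inherits(model, "vc_hh_ina")) {
    inf <- ina_gate_inf(model, Vm)
    model$g_max * inf$m^3 * inf$h * inf$j * (Vm - model$E_Na)
  } else if (inherits(model, "vc_model_cell")) {
    Vm / model$Rm
  } else if (inherits(model, "vc_null_model")) {
    rep(0, length(Vm))
  } else {
    vapply(Vm, function(v) {
      ionic_current(model, v, ionic_steady_states(model, v))
    }, numeric(1))
  }
}

new_trace <- function(df, settings = NULL, cell = NULL, model = NULL,
                      protocol = NULL) {
  out <- tibble::as_tibble(df)
  class(out) <- c("vc_trace", class(out))
  attr(out, "settings") <- settings
  attr(out, "cell") <- cell
  attr(out, "model") <- model
  attr(out, "protocol") <- protocol
  out
}

segment_times <- function(duration, dt) {
  tt <- seq(0, duration, by = dt)
  if (tt[length(tt)] < duration) tt <- c(tt, duration)
  tt
}

#' Simulate a voltage-clamp experiment with artefacts
#'
#' Integrates the coupled cell-amplifier model over a step protocol, starting
#' from the steady state at the protocol's first (holding) level. Command
#' steps are instantaneous; the integrator is re-initialised at each segment
#' boundary so the discontinuity is honoured exactly (the amplifier time
#' constants provide the physical smoothing). The system is stiff —
#' microsecond amplifier lags alongside millisecond gating — and is solved
#' with an implicit multistep method via compiled derivatives.
#'
#' @inheritParams artefact_rhs
#' @param protocol A `vc_protocol` tibble (see [protocol()]).
#' @param dt_out Output sampling interval (ms). The default 0.01 ms resolves
#'   the `tau_z`-filtered capacitive spikes.
#' @param dt_hold Optional coarser sampling interval for the first (holding)
#'   segment, which starts at steady state and carries no dynamics; useful
#'   for protocols with multi-second holds.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param method deSolve integration method (default `"lsoda"`, which runs
#'   BDF on the stiff portions).
#' @return A `vc_trace` tibble with columns `time_ms`, `vcmd_mV`, `vm_mV`,
#'   `vp_mV`, `vclamp_mV`, `vest_mV`, `iion_nA`, `iout_nA`, `ipost_nA`
#'   (leak-subtracted using the amplifier's `gleak_est`, `Eleak_est`).
#' @examples
#' tr <- simulate_clamp(amplifier_settings(), cell_properties(Rs = 5),
#'                      model_cell(), step_protocol(), dt_out = 0.05)
#' @export
simulate_clamp <- function(settings, cell, model, protocol,
                           dt_out = 0.01, dt_hold = NULL,
                           rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(inherits(protocol, "vc_protocol"), nrow(protocol) >= 1,
            dt_out > 0)
  if (!.vc_compiled(model)) {
    return(simulate_clamp_r(settings, cell, model, protocol, dt_out, dt_hold,
                            rtol, atol, method))
  }
  y <- steady_state_init(settings, cell, model, protocol$level_mV[1])
  pieces <- vector("list", nrow(protocol))
  t0 <- 0
  for (i in seq_len(nrow(protocol))) {
    lev <- protocol$level_mV[i]
    dur <- protocol$duration_ms[i]
    dt <- if (i == 1 && !is.null(dt_hold)) dt_hold else dt_out
    tt <- segment_times(dur, dt)
    parms <- .vc_parms(settings, cell, model, lev)
    sol <- deSolve::ode(y = y, times = tt, func = "vc_derivs", parms = parms,
                        dllname = "voltclamp", initfunc = "vc_initmod",
                        method = method, rtol = rtol, atol = atol,
                        maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[nrow(sol), -1]))) {
      stop(sprintf(
        "Integration failed near t = %.4f ms (segment %d, Vcmd = %g mV).",
        t0 + sol[max(which(is.finite(sol[, 2]))), 1], i, lev), call. = FALSE)
    }
    y <- sol[nrow(sol), -1]
    keep <- if (i < nrow(protocol)) seq_len(nrow(sol) - 1) else seq_len(nrow(sol))
    pieces[[i]] <- cbind(time_ms = t0 + sol[keep, 1], vcmd_mV = lev,
                         sol[keep, -1, drop = FALSE])
    t0 <- t0 + dur
  }
  m <- do.call(rbind, pieces)
  iion <- trace_ionic_current(model, m[, "Vm"], m[, -(1:7), drop = FALSE])
  df <- tibble::tibble(
    time_ms = m[, "time_ms"], vcmd_mV = m[, "vcmd_mV"],
    vm_mV = m[, "Vm"], vp_mV = m[, "Vp"], vclamp_mV = m[, "Vclamp"],
    vest_mV = m[, "Vest"], iion_nA = iion, iout_nA = m[, "Iout"],
    ipost_nA = m[, "Iout"] -
      settings$gleak_est * (m[, "vcmd_mV"] - settings$Eleak_est)
  )
  new_trace(df, settings, cell, model, protocol)
}

# Vectorised ionic current from a matrix of ionic state columns.
trace_ionic_current <- function(model, vm, states) {
  if (inherits(model, "vc_model_cell")) {
    states[, 1] + vm / model$Rm
  } else if (inherits(model, "vc_hh_ina")) {
    model$g_max * states[, 1]^3 * states[, 2] * states[, 3] * (vm - model$E_Na)
  } else if (inherits(model, "vc_null_model")) {
    rep(0, length(vm))
  } else {
    vapply(seq_along(vm),
           function(i) ionic_current(model, vm[i], states[i, ]), numeric(1))
  }
}

# Fallback integration through the R-level right-hand side, for plug-in
# ionic models without compiled support.
simulate_clamp_r <- function(settings, cell, model, protocol, dt_out, dt_hold,
                             rtol, atol, method) {
  y <- steady_state_init(settings, cell, model, protocol$level_mV[1])
  pieces <- vector("list", nrow(protocol))
  t0 <- 0
  for (i in seq_len(nrow(protocol))) {
    lev <- protocol$level_mV[i]
    dur <- protocol$duration_ms[i]
    dt <- if (i == 1 && !is.null(dt_hold)) dt_hold else dt_out
    tt <- segment_times(dur, dt)
    fn <- function(t, y, parms) {
      list(artefact_rhs(y, t, settings, cell, model, lev)$deriv)
    }
    sol <- deSolve::ode(y = y, times = tt, func = fn, parms = NULL,
                        method = method, rtol = rtol, atol = atol,
                        maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[nrow(sol), -1]))) {
      stop(sprintf("Integration failed near t = %.4f ms (segment %d).",
                   t0 + sol[nrow(sol), 1], i), call. = FALSE)
    }
    y <- sol[nrow(sol), -1]
    keep <- if (i < nrow(protocol)) seq_len(nrow(sol) - 1) else seq_len(nrow(sol))
    pieces[[i]] <- cbind(time_ms = t0 + sol[keep, 1], vcmd_mV = lev,
                         sol[keep, -1, drop = FALSE])
    t0 <- t0 + dur
  }
  m <- do.call(rbind, pieces)
  iion <- trace_ionic_current(model, m[, "Vm"], m[, -(1:7), drop = FALSE])
  df <- tibble::tibble(
    time_ms = m[, "time_ms"], vcmd_mV = m[, "vcmd_mV"],
    vm_mV = m[, "Vm"], vp_mV = m[, "Vp"], vclamp_mV = m[, "Vclamp"],
    vest_mV = m[, "Vest"], iion_nA = iion, iout_nA = m[, "Iout"],
    ipost_nA = m[, "Iout"] -
      settings$gleak_est * (m[, "vcmd_mV"] - settings$Eleak_est)
  )
  new_trace(df, settings, cell, model, protocol)
}

#' Simulate an ideal (artefact-free) voltage clamp
#'
#' Integrates only the ionic states with the membrane voltage identically
#' equal to the command: `Vm == Vcmd`, `Iout == Ipost == Iion`. This is the
#' artefact-free reference against which recorded or simulated currents are
#' compared. For Hodgkin-Huxley models the gating relaxations within each
#' constant-voltage segment are computed in closed form; for the model cell
#' the series RC branch jumps by `dV/Rk` at each step and then decays with
#' `Rk*Ck`; other models are integrated numerically.
#'
#' @inheritParams simulate_clamp
#' @return A `vc_trace` tibble (voltage columns all equal the command).
#' @examples
#' simulate_ideal(model_cell(), step_protocol(), dt_out = 0.1)
#' @export
simulate_ideal <- function(model, protocol, dt_out = 0.01, dt_hold = NULL) {
  stopifnot(inherits(protocol, "vc_protocol"), nrow(protocol) >= 1,
            dt_out > 0)
  states <- ionic_steady_states(model, protocol$level_mV[1])
  v_prev <- protocol$level_mV[1]
  pieces <- vector("list", nrow(protocol))
  t0 <- 0
  for (i in seq_len(nrow(protocol))) {
    lev <- protocol$level_mV[i]
    dur <- protocol$duration_ms[i]
    dt <- if (i == 1 && !is.null(dt_hold)) dt_hold else dt_out
    tt <- segment_times(dur, dt)
    states <- on_voltage_jump(model, states, lev - v_prev)
    seg <- ideal_segment(model, lev, states, tt)
    states <- seg$final
    keep <- if (i < nrow(protocol)) seq_len(length(tt) - 1) else seq_along(tt)
    pieces[[i]] <- data.frame(time_ms = t0 + tt[keep], vcmd_mV = lev,
                              iion_nA = seg$iion[keep])
    v_prev <- lev
    t0 <- t0 + dur
  }
  df <- do.call(rbind, pieces)
  out <- tibble::tibble(
    time_ms = df$time_ms, vcmd_mV = df$vcmd_mV, vm_mV = df$vcmd_mV,
    vp_mV = df$vcmd_mV, vclamp_mV = df$vcmd_mV, vest_mV = df$vcmd_mV,
    iion_nA = df$iion_nA, iout_nA = df$iion_nA, ipost_nA = df$iion_nA
  )
  new_trace(out, settings = NULL, cell = NULL, model = model,
            protocol = protocol)
}

# Ionic current along one constant-voltage segment of an ideal clamp.
ideal_segment <- function(model, V, states, tt) {
  if (inherits(model, "vc_hh_ina")) {
    inf <- ina_gate_inf(model, V)
    tau <- ina_gate_tau(model, V)
    m <- inf$m + (states[[1]] - inf$m) * exp(-tt / tau$m)
    h <- inf$h + (states[[2]] - inf$h) * exp(-tt / tau$h)
    j <- inf$j + (states[[3]] - inf$j) * exp(-tt / tau$j)
    n <- length(tt)
    list(iion = model$g_max * m^3 * h * j * (V - model$E_Na),
         final = c(m = m[n], h = h[n], j = j[n]))
  } else if (inherits(model, "vc_model_cell")) {
    tau <- model$Rk * pf_to_nf(model$Ck)
    ik <- states[[1]] * exp(-tt / tau)
    list(iion = ik + V / model$Rm, final = c(Ik = ik[length(tt)]))
  } else if (inherits(model, "vc_null_model")) {
    list(iion = rep(0, length(tt)), final = states)
  } else {
    fn <- function(t, y, parms) list(ionic_rhs(model, V, y, 0, t)$deriv)
    sol <- deSolve::ode(y = states, times = tt, func = fn, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
    ss <- sol[, -1, drop = FALSE]
    list(iion = trace_ionic_current(model, rep(V, length(tt)), ss),
         final = sol[nrow(sol), -1])
  }
}

#' Leak-subtract a recorded or simulated trace
#'
#' Fills the post-processed current `Ipost(t) = Iout(t) - gleak_est *
#' (Vcmd(t) - Eleak_est)`, the standard off-line leak correction using the
#' machine's leak estimates.
#'
#' @param trace A `vc_trace` tibble with `iout_nA` and `vcmd_mV` columns.
#' @param settings [amplifier_settings()] supplying `gleak_est` and
#'   `Eleak_est`; defaults to the settings the trace was simulated with.
#' @return The trace with `ipost_nA` (re)computed.
#' @export
leak_subtract <- function(trace, settings = NULL) {
  settings <- settings %||% attr(trace, "settings")
  if (is.null(settings)) {
    stop("`settings` must be supplied for a trace without embedded ",
         "amplifier settings.", call. = FALSE)
  }
  trace$ipost_nA <- trace$iout_nA -
    settings$gleak_est * (trace$vcmd_mV - settings$Eleak_est)
  trace
}

`%||%` <- function(a, b) if (is.null(a)) b else a
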