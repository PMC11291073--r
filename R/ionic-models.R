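#' Ionic current models
#'
#' The artefact simulator is agnostic to the ionic current flowing across the
#' membrane: any object implementing the small generic interface below can be
#' attached. Two concrete models ship with the package:
#'
#' * [model_cell()] — an electrical "model cell": a resistor `Rm` in parallel
#'   with a series resistor-capacitor branch (`Rk`, `Ck`). Because it is
#'   linear, the whole coupled cell-amplifier system admits a closed-form
#'   solution ([simulate_model_cell_exact()]), making it the validation
#'   workhorse.
#' * [generic_ina()] — a generic Hodgkin-Huxley fast sodium current with
#'   `m^3 * h * j` gating, standing in for published cardiac INa models.
#'
#' The interface consists of [n_states()], [ionic_current()], [ionic_rhs()],
#' [ionic_steady_states()] and [on_voltage_jump()].
#'
#' @name ionic_models
NULL

#' Electrical model cell (linear RC network)
#'
#' A two-branch linear circuit standing in for a biological cell: a static
#' membrane resistor `Rm` carrying `Im = Vm / Rm`, in parallel with a dynamic
#' branch (`Rk` in series with `Ck`) carrying a current `Ik` that relaxes with
#' time constant `Rk * Ck`. The total "ionic" current is `Ik + Im`. With the
#' defaults the relaxation time constant is `100 MOhm * 10 pF = 1 ms` and a
#' 130 mV step drives a current of order 10 nA, comparable in size and speed
#' to a fast sodium current.
#'
#' The dynamic branch depends on `dVm/dt`; the coupled simulator evaluates
#' the membrane equation first and feeds its derivative into this branch in
#' the same right-hand-side evaluation (no numerical differentiation).
#'
#' @param Rk Resistance of the dynamic branch (MOhm).
#' @param Ck Capacitance of the dynamic branch (pF).
#' @param Rm Static membrane resistance (MOhm).
#' @return An object of classes `vc_model_cell`, `vc_ionic_model`.
#' @examples
#' mc <- model_cell()
#' ionic_current(mc, Vm = 50, states = c(Ik = 0))  # 50 / Rm = 5 nA
#' @export
model_cell <- function(Rk = 100, Ck = 10, Rm = 10) {
  check_positive(c(Rk = Rk, Ck = Ck, Rm = Rm))
  structure(list(Rk = Rk, Ck = Ck, Rm = Rm),
            class = c("vc_model_cell", "vc_ionic_model"))
}

#' Generic Hodgkin-Huxley fast sodium current
#'
#' An `INa = g_max * m^3 * h * j * (Vm - E_Na)` formulation with sigmoidal
#' steady-state (in)activation and bell-shaped voltage-dependent time
#' constants,
#' `tau_x(V) = min + amp / (exp((V - vmid)/sigma) + exp(-(V - vmid)/sigma))`.
#' The defaults place the activation threshold near -40 mV and the
#' ideal-clamp I-V peak at -20 mV with a flat top towards -10 mV (the
#' typical placement for a cardiac fast sodium current), and make
#' activation steep (e-fold per ~4.5 mV on `m_inf`, considerably steeper on
#' `m^3`), reproducing the positive-feedback interplay between inward
#' current and series-resistance voltage error that delays near-threshold
#' peaks and skews population I-V comparisons.
#'
#' @param g_max Maximal conductance (uS).
#' @param E_Na Reversal potential (mV).
#' @param act_vhalf,act_slope Half-activation voltage (mV) and slope factor
#'   (mV) of `m_inf`.
#' @param inact_vhalf,inact_slope Half-inactivation voltage (mV) and slope
#'   factor (mV) of `h_inf` (shared by the slow gate `j`).
#' @param tau_m,tau_h,tau_j Numeric length-4 vectors `(min, amp, vmid, sigma)`
#'   for the bell-shaped time constants, in ms (min, amp) and mV (vmid,
#'   sigma). The maximum of each bell is `min + amp/2` at `V = vmid`.
#' @return An object of classes `vc_hh_ina`, `vc_ionic_model`.
#' @examples
#' ina <- generic_ina(g_max = 0.6)
#' ionic_steady_states(ina, Vm = -100)
#' @export
generic_ina <- function(g_max = 0.6, E_Na = 60,
                        act_vhalf = -34, act_slope = 4.5,
                        inact_vhalf = -68, inact_slope = 6.1,
                        tau_m = c(0.12, 0.6, -50, 18),
                        tau_h = c(0.4, 6, -65, 14),
                        tau_j = c(1.5, 60, -65, 14)) {
  check_positive(c(E_Na_defined = 1, act_slope = act_slope,
                   inact_slope = inact_slope))
  check_nonnegative(c(g_max = g_max))
  for (nm in c("tau_m", "tau_h", "tau_j")) {
    v <- get(nm)
    if (length(v) != 4 || any(!is.finite(v)) || v[1] <= 0 || v[2] < 0 ||
        v[4] <= 0) {
      stop("`", nm, "` must be (min > 0, amp >= 0, vmid, sigma > 0).",
           call. = FALSE)
    }
  }
  structure(list(g_max = g_max, E_Na = E_Na,
                 act_vhalf = act_vhalf, act_slope = act_slope,
                 inact_vhalf = inact_vhalf, inact_slope = inact_slope,
                 tau_m = tau_m, tau_h = tau_h, tau_j = tau_j),
            class = c("vc_hh_ina", "vc_ionic_model"))
}

#' Empty ionic model (passive cell)
#'
#' Carries no transmembrane ionic current at all; the cell then consists only
#' of its capacitance and seal leak. Useful for isolating instrument effects.
#'
#' @return An object of classes `vc_null_model`, `vc_ionic_model`.
#' @export
no_ionic_model <- function() {
  structure(list(), class = c("vc_null_model", "vc_ionic_model"))
}

# ---- generic interface -----------------------------------------------------

#' Number of ionic state variables
#' @param model An ionic model object.
#' @return Integer count of the model's internal states.
#' @export
n_states <- function(model) UseMethod("n_states")

#' @export
n_states.vc_model_cell <- function(model) 1L

#' @export
n_states.vc_hh_ina <- function(model) 3L

#' @export
n_states.vc_null_model <- function(model) 0L

#' Ionic current at a given membrane voltage and state
#' @param model An ionic model object.
#' @param Vm Membrane voltage (mV).
#' @param states Numeric vector of ionic states (length [n_states()]).
#' @param t Time (ms); unused by the built-in autonomous models.
#' @return Current in nA (inward negative).
#' @export
ionic_current <- function(model, Vm, states, t = 0) UseMethod("ionic_current")

#' @export
ionic_current.vc_model_cell <- function(model, Vm, states, t = 0) {
  states[[1]] + Vm / model$Rm
}

#' @export
ionic_current.vc_hh_ina <- function(model, Vm, states, t = 0) {
  model$g_max * states[[1]]^3 * states[[2]] * states[[3]] * (Vm - model$E_Na)
}

#' @export
ionic_current.vc_null_model <- function(model, Vm, states, t = 0) 0

#' Ionic state derivatives
#'
#' @inheritParams ionic_current
#' @param dVm_dt Time derivative of the membrane voltage (mV/ms). Required by
#'   models with a capacitive branch (the model cell); ignored otherwise.
#' @return A list with elements `current` (nA) and `deriv` (numeric vector of
#'   state derivatives, 1/ms units as appropriate).
#' @export
ionic_rhs <- function(model, Vm, states, dVm_dt = 0, t = 0) UseMethod("ionic_rhs")

#' @export
ionic_rhs.vc_model_cell <- function(model, Vm, states, dVm_dt = 0, t = 0) {
  ck_nf <- pf_to_nf(model$Ck)
  tau <- model$Rk * ck_nf                       # ms
  list(current = states[[1]] + Vm / model$Rm,
       deriv = c(Ik = (ck_nf * dVm_dt - states[[1]]) / tau))
}

#' @export
ionic_rhs.vc_hh_ina <- function(model, Vm, states, dVm_dt = 0, t = 0) {
  inf <- ina_gate_inf(model, Vm)
  tau <- ina_gate_tau(model, Vm)
  list(current = ionic_current(model, Vm, states),
       deriv = c(m = (inf$m - states[[1]]) / tau$m,
                 h = (inf$h - states[[2]]) / tau$h,
                 j = (inf$j - states[[3]]) / tau$j))
}

#' @export
ionic_rhs.vc_null_model <- function(model, Vm, states, dVm_dt = 0, t = 0) {
  list(current = 0, deriv = numeric(0))
}

#' Ionic states at equilibrium for a fixed membrane voltage
#' @inheritParams ionic_current
#' @return Named numeric vector of states with zero time derivative at `Vm`
#'   (holding `dVm/dt = 0`).
#' @export
ionic_steady_states <- function(model, Vm) UseMethod("ionic_steady_states")

#' @export
ionic_steady_states.vc_model_cell <- function(model, Vm) c(Ik = 0)

#' @export
ionic_steady_states.vc_hh_ina <- function(model, Vm) {
  inf <- ina_gate_inf(model, Vm)
  c(m = inf$m, h = inf$h, j = inf$j)
}

#' @export
ionic_steady_states.vc_null_model <- function(model, Vm) numeric(0)

#' State update across an instantaneous voltage step (ideal clamp)
#'
#' Under an ideal clamp the membrane voltage is discontinuous at protocol
#' boundaries. Models whose states depend on `dVm/dt` must integrate the
#' resulting impulse: for the model cell's series RC branch a step of `dV`
#' makes `Ik` jump by `dV / Rk`. Gating-variable models are continuous and
#' return their states unchanged.
#'
#' @param model An ionic model object.
#' @param states Ionic states immediately before the step.
#' @param dV Voltage step size (mV).
#' @return Updated state vector immediately after the step.
#' @export
on_voltage_jump <- function(model, states, dV) UseMethod("on_voltage_jump")

#' @export
on_voltage_jump.default <- function(model, states, dV) states

#' @export
on_voltage_jump.vc_model_cell <- function(model, states, dV) {
  states[[1]] <- states[[1]] + dV / model$Rk
  states
}

# ---- HH gating helpers (vectorised over V) ---------------------------------

ina_gate_inf <- function(model, V) {
  list(m = 1 / (1 + exp(-(V - model$act_vhalf) / model$act_slope)),
       h = 1 / (1 + exp((V - model$inact_vhalf) / model$inact_slope)),
       j = 1 / (1 + exp((V - model$inact_vhalf) / model$inact_slope)))
}

ina_gate_tau <- function(model, V) {
  bell <- function(q) {
    z <- (V - q[3]) / q[4]
    q[1] + q[2] / (exp(z) + exp(-z))
  }
  list(m = bell(model$tau_m), h = bell(model$tau_h), j = bell(model$tau_j))
}

#' Convert a current density to a maximal conductance
#'
#' Expression-system studies often prescribe the current size as a density
#' (A/F); the simulator works in conductance (uS). The conversion fixes
#' `g_max` so that the largest ideal-clamp peak current across the protocol
#' family, per unit membrane capacitance, equals the requested density. Peak
#' current is linear in `g_max` under ideal clamp, so the conversion is a
#' single division by the unit-conductance peak.
#'
#' @param density Current density (A/F), non-negative.
#' @param Cm Membrane capacitance (pF).
#' @param model Ionic model whose conductance is to be scaled (its own
#'   `g_max` is ignored).
#' @param protocols Protocol family over which the peak is taken; defaults to
#'   the package's standard sodium I-V family.
#' @param dt_out Output sampling interval for the peak search (ms).
#' @return `g_max` in uS.
#' @examples
#' density_to_conductance(1500, Cm = 40)
#' @export
density_to_conductance <- function(density, Cm, model = generic_ina(),
                                   protocols = iv_protocols(),
                                   dt_out = 0.01) {
  stopifnot(is.numeric(density), length(density) == 1, is.finite(density),
            density >= 0)
  check_positive(c(Cm = Cm))
  if (density == 0) return(0)
  peak_unit <- unit_peak_current(model, protocols, dt_out)
  # density [A/F] * Cm [pF] = pA -> nA
  density * Cm * 1e-3 / peak_unit
}

# Largest |ideal-clamp peak current| over the protocol family at g_max = 1 uS.
unit_peak_current <- function(model, protocols, dt_out = 0.01) {
  stopifnot(inherits(model, "vc_hh_ina"))
  m1 <- model
  m1$g_max <- 1
  traces <- lapply(protocols, function(p) simulate_ideal(m1, p, dt_out = dt_out,
                                                         dt_hold = 1))
  iv <- compute_iv(traces, protocols)
  max(abs(iv$peak_current_nA))
}
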