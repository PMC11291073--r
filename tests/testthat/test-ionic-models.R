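test_that("model cell currents follow the two-branch circuit", {
  mc <- model_cell()
  expect_equal(ionic_current(mc, Vm = 50, states = c(Ik = 0)), 5)
  expect_equal(ionic_current(mc, Vm = 0, states = c(Ik = 0)), 0)
  r <- ionic_rhs(mc, Vm = 0, states = c(Ik = 2), dVm_dt = 0)
  expect_equal(unname(r$deriv), -2 / 1)   # relaxation constant Rk*Ck = 1 ms
  # an ideal -80 -> 50 step swings the total current by order 10 nA
  tr <- simulate_ideal(mc, rig_protocol(), dt_out = 0.05)
  swing <- diff(range(tr$iion_nA))
  expect_gt(swing, 10)
  expect_lt(swing, 100)
})

test_that("ideal-clamp Ik relaxes with the circuit time constant", {
  tr <- simulate_ideal(model_cell(), rig_protocol(), dt_out = 0.01)
  step <- tr[tr$time_ms >= 20 & tr$time_ms < 40, ]
  ik <- step$iion_nA - step$vcmd_mV / 10   # subtract the Rm branch
  tau <- fit_exp_tau(step$time_ms - 20, ik)
  expect_equal(tau, 1, tolerance = 1e-6)
})

test_that("every ionic model is at equilibrium after steady_states", {
  for (model in list(model_cell(), generic_ina(), no_ionic_model())) {
    for (v in seq(-120, 40, by = 20)) {
      ss <- ionic_steady_states(model, v)
      expect_length(ss, n_states(model))
      d <- ionic_rhs(model, v, ss, dVm_dt = 0)$deriv
      expect_lt(max(abs(d), 0), 1e-8)
    }
  }
})

test_that("generic INa has zero driving force at E_Na and a quiet subthreshold foot", {
  ina <- generic_ina(g_max = 0.6)
  expect_equal(ionic_current(ina, ina$E_Na, c(m = 1, h = 1, j = 1)), 0)
  # held far below threshold the open fraction stays negligible
  for (v in c(-80, -60, -50)) {
    ss <- ionic_steady_states(ina, v)
    expect_lt(abs(ionic_current(ina, v, ss)),
              0.01 * ina$g_max * abs(v - ina$E_Na))
  }
})

test_that("ideal-clamp INa I-V is biphasic with a single interior peak", {
  ina <- generic_ina()
  prs <- iv_protocols(-100, 50, -80, 60, 10, 20)
  iv <- simulate_iv(NULL, NULL, ina, prs, ideal = TRUE, dt_out = 0.02,
                    dt_hold = 1)
  k <- which.min(iv$peak_current_nA)
  expect_gt(k, 1)
  expect_lt(k, nrow(iv))
  # monotone approach on both flanks of the peak
  expect_true(all(diff(iv$peak_current_nA[1:k]) < 0))
  expect_true(all(diff(iv$peak_current_nA[k:nrow(iv)]) > 0))
  # designed placement: peak at -20 mV, threshold near -40 mV
  expect_equal(iv$voltage_mV[k], -20)
})

test_that("gating variables stay within [0, 1] along artefact-model trajectories", {
  ina <- generic_ina(g_max = 1)
  for (a in c(0, 0.8)) {
    tr <- simulate_clamp(ina_settings(a, a), ina_cell(), ina,
                         step_protocol(-100, 5, -20, 10, 5), dt_out = 0.05)
    # open fraction m^3 h j recovered from the current must lie in [0, 1]
    drive <- tr$vm_mV - ina$E_Na
    open_frac <- tr$iion_nA / (ina$g_max * drive)
    open_frac <- open_frac[abs(drive) > 1]
    expect_true(all(open_frac >= -1e-9 & open_frac <= 1 + 1e-9))
  }
})

test_that("density-to-conductance conversion is linear and exact in ratio", {
  expect_equal(density_to_conductance(0, 20), 0)
  prs <- iv_protocols(-100, 50, -60, 30, 10, 10)
  g1 <- density_to_conductance(500, 10, protocols = prs, dt_out = 0.02)
  g2 <- density_to_conductance(500, 20, protocols = prs, dt_out = 0.02)
  g3 <- density_to_conductance(1500, 20, protocols = prs, dt_out = 0.02)
  expect_equal(g2, 2 * g1)           # doubling Cm doubles g
  expect_equal(g3 / g2, 3)           # 1500 vs 500 A/F -> ratio exactly 3
  # round trip: the conversion reproduces the requested density
  ina <- generic_ina(g_max = g3)
  iv <- simulate_iv(NULL, NULL, ina, prs, ideal = TRUE, dt_out = 0.02,
                    dt_hold = 1)
  expect_equal(max(abs(iv$peak_current_nA)) / (20 * 1e-3), 1500,
               tolerance = 1e-6)
  expect_error(density_to_conductance(100, -5), "Cm")
})

test_that("model-cell superposition holds through the full coupled system", {
  s <- rig_settings(0.6, 0.6)
  cl <- rig_cell()      # gleak = 0, Voff = 0: the system is strictly linear
  p1 <- step_protocol(-80, 5, 50, 10, 5)
  p2 <- step_protocol(-40, 5, 25, 10, 5)  # half the levels everywhere
  t1 <- simulate_clamp(s, cl, model_cell(), p1, dt_out = 0.05)
  t2 <- simulate_clamp(s, cl, model_cell(), p2, dt_out = 0.05)
  expect_lt(trace_rel_error(t1, dplyr::mutate(t2,
    vm_mV = 2 * vm_mV, vp_mV = 2 * vp_mV, vclamp_mV = 2 * vclamp_mV,
    vest_mV = 2 * vest_mV, iout_nA = 2 * iout_nA)), 1e-7)
})
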