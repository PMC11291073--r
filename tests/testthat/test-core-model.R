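test_that("zero compensation reduces the effective command to the command itself", {
  s <- rig_settings(0, 0)
  cl <- rig_cell()
  st <- c(Vm = -12, Vp = -70, Vclamp = -75, Vest = -60, Iout = 1.5, Ik = 0.3)
  r <- artefact_rhs(st, 0, s, cl, model_cell(), Vcmd = -80)
  expect_equal(r$Vcmd_prime, -80)
  # dVest/dt = (Vcmd - Vest) / (Rs* Cm*) with both alphas zero
  expect_equal(r$deriv[["Vest"]], (-80 - (-60)) / (30 * 22e-3))
})

test_that("the supercharging estimate is at a fixed point when it equals the command", {
  s <- rig_settings(0.5, 0.8)
  st <- c(Vm = 0, Vp = 0, Vclamp = 0, Vest = -80, Iout = 0, Ik = 0)
  r <- artefact_rhs(st, 0, s, rig_cell(), model_cell(), Vcmd = -80)
  expect_equal(r$deriv[["Vest"]], 0)
  expect_equal(r$Vcmd_prime, -80)  # supercharging term vanishes with dVest = 0
})

test_that("model-cell RHS equals the hand-assembled affine system at random states", {
  withr::with_seed(7, {
    for (i in 1:5) {
      s <- rig_settings(runif(1, 0, 0.9), runif(1, 0, 0.9))
      cl <- rig_cell(gleak = runif(1, 0, 0.01), Eleak = runif(1, -5, 5),
                     Voff = runif(1, -5, 5))
      sys <- model_cell_system(s, cl, model_cell())
      x <- rnorm(6, sd = 20)
      names(x) <- c("Vm", "Vp", "Vclamp", "Vest", "Iout", "Ik")
      vcmd <- runif(1, -100, 60)
      r <- artefact_rhs(x, 0, s, cl, model_cell(), vcmd)
      expected <- as.vector(sys$A %*% x + sys$b * vcmd + sys$c0)
      expect_equal(unname(r$deriv), expected, tolerance = 1e-12)
    }
  })
})

test_that("compiled and R-level derivatives integrate to the same trajectories", {
  # same equations, two independent code paths (C vs R closures)
  s <- ina_settings(0.7, 0.7, gleak_est = 0.001)
  cl <- ina_cell(gleak = 0.001, Voff = 1.5)
  pr <- step_protocol(-80, 2, -20, 5, 2)
  for (model in list(generic_ina(g_max = 0.4), model_cell())) {
    fast <- simulate_clamp(s, cl, model, pr, dt_out = 0.05)
    slow <- voltclamp:::simulate_clamp_r(s, cl, model, pr, 0.05, NULL,
                                         1e-8, 1e-10, "lsoda")
    expect_lt(trace_rel_error(fast, slow), 1e-6)
  }
})

test_that("with a tiny series resistance the measured current tracks the ideal current", {
  ina <- generic_ina(g_max = 0.5)
  # amplifier lags at their minimal settings, so the series-resistance
  # limit being probed is not masked by the fixed instrument delays
  s <- amplifier_settings(0, 0, Rs_est = 1e-3, Cm_est = 30, Cp_est = 0,
                          tau_sum = 2e-4, tau_clamp = 2e-4, tau_z = 2e-4)
  cl <- cell_properties(Rs = 1e-3, Cm = 30, Cp = 0, gleak = 0, Voff = 0)
  pr <- step_protocol(-80, 2, -10, 10, 2)
  tr <- simulate_clamp(s, cl, ina, pr, dt_out = 0.01)
  ideal <- simulate_ideal(ina, pr, dt_out = 0.01)
  # compare after the brief residual capacitive transient has settled
  after <- tr$time_ms > 2.05 & tr$time_ms < 12
  err <- max(abs(tr$iout_nA[after] - ideal$iout_nA[after]))
  expect_lt(err, 0.01 * max(abs(ideal$iout_nA)))
})

test_that("leak subtraction follows the machine's leak estimate pointwise", {
  tr <- new_trace <- tibble::tibble(
    time_ms = 0:3, vcmd_mV = c(0, 50, 50, 0), vm_mV = 0, vp_mV = 0,
    vclamp_mV = 0, vest_mV = 0, iion_nA = 0, iout_nA = 2, ipost_nA = NA_real_)
  class(tr) <- c("vc_trace", class(tr))
  s0 <- amplifier_settings(gleak_est = 0)
  expect_equal(leak_subtract(tr, s0)$ipost_nA, tr$iout_nA)
  s1 <- amplifier_settings(gleak_est = 0.01, Eleak_est = 0)
  expect_equal(leak_subtract(tr, s1)$ipost_nA[2], 2 - 0.01 * 50)  # 1.5 nA
})

test_that("with perfect leak estimates Ipost recovers Iion at steady state", {
  s <- rig_settings(gleak_est = 0.005, Eleak_est = -3)
  cl <- rig_cell(gleak = 0.005, Eleak = -3, Cp = 0)
  pr <- step_protocol(-80, 30, 50, 30, 0)
  tr <- simulate_clamp(s, cl, model_cell(), pr, dt_out = 0.05)
  # late in the step the cell has settled; under zero compensation Vm != Vcmd,
  # so compare against the ionic current through the true Vm
  late <- tr[tr$time_ms > 55, ]
  expect_equal(late$ipost_nA,
               late$iion_nA + cl$gleak * (late$vm_mV - cl$Eleak) -
                 s$gleak_est * (late$vcmd_mV - s$Eleak_est),
               tolerance = 1e-6)
})

test_that("steady-state initialisation zeroes the full right-hand side", {
  # trivial symmetric case: everything at rest is exactly zero
  st0 <- steady_state_init(rig_settings(), rig_cell(), model_cell(), 0)
  expect_equal(unname(st0), rep(0, 6), tolerance = 1e-12,
               ignore_attr = TRUE)

  # holding at -80: matches the closed-form equilibrium of the affine system
  s <- rig_settings(0.4, 0.3)
  cl <- rig_cell(gleak = 0.002, Voff = 2)
  st <- steady_state_init(s, cl, model_cell(), -80)
  sys <- model_cell_system(s, cl, model_cell())
  expect_equal(unname(st), unname(model_cell_equilibrium(sys, -80)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(attr(st, "residual"), 1e-8)

  # the residual contract holds for the nonlinear sodium system too
  st2 <- steady_state_init(ina_settings(0.8, 0.8), ina_cell(Voff = -2),
                           generic_ina(), -100)
  expect_lt(attr(st2, "residual"), 1e-8)
})

test_that("a residual offset shifts the passive membrane by the seal divider", {
  # passive cell: seal leak only; equilibrium Vm = Voff * Rseal/(Rs + Rseal)
  voff <- 7
  cl <- cell_properties(Rs = 20, Cm = 30, Cp = 0, gleak = 0.004, Eleak = 0,
                        Voff = voff)
  st <- steady_state_init(amplifier_settings(), cl, no_ionic_model(), 0)
  rseal <- 1 / cl$gleak
  expect_equal(st[["Vm"]], voff * rseal / (cl$Rs + rseal), tolerance = 1e-9)
})

test_that("integration failures name the failing segment", {
  # an unsatisfiable tolerance forces the solver to give up
  expect_error(
    suppressWarnings(
      simulate_clamp(rig_settings(0.9, 0.9), rig_cell(), model_cell(),
                     rig_protocol(), dt_out = 0.1, rtol = 1e-15,
                     atol = 1e-300)),
    "Integration failed")
})
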