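test_that("compensation sweeps reproduce the three grid layouts", {
  s <- rig_settings()
  pr <- step_protocol(-80, 5, 50, 10, 5)
  sw <- compensation_sweep(s, rig_cell(), model_cell(), pr,
                           alpha_R = c(0, 0.4, 0.8), alpha_P = 0,
                           dt_out = 0.1)
  expect_equal(nrow(sw), 3)
  expect_equal(sw$alpha_P, rep(0, 3))
  # the zero-compensation entry is a plain simulation
  plain <- simulate_clamp(s, rig_cell(), model_cell(), pr, dt_out = 0.1)
  expect_equal(sw$trace[[1]]$iout_nA, plain$iout_nA)
  # joint grid: both levels move together
  sw3 <- compensation_sweep(s, rig_cell(), model_cell(), pr,
                            alpha_R = c(0, 0.8), alpha_P = c(0, 0.8),
                            dt_out = 0.1)
  expect_equal(sw3$alpha_R, sw3$alpha_P)
  expect_error(compensation_sweep(s, rig_cell(), model_cell(), pr,
                                  alpha_R = 0.99), "0.95")
})

test_that("the mean/variance log-normal sampler matches its stated moments", {
  withr::with_seed(11, {
    x <- rlnorm_meanvar(2e5, mean = 2.5, var = 1.5)
    expect_equal(mean(x), 2.5, tolerance = 0.02)
    expect_equal(var(x), 1.5, tolerance = 0.05)
    y <- rlnorm_meanvar(2e5, mean = 40, var = 10)
    expect_equal(mean(y), 40, tolerance = 0.01)
  })
})

test_that("the averaging study is deterministic and validates its inputs", {
  prs <- iv_protocols(-100, 20, -40, 0, 20, 10)  # small family for speed
  a <- averaging_study(n = 3, seed = 5, protocols = prs, dt_out = 0.05)
  b <- averaging_study(n = 3, seed = 5, protocols = prs, dt_out = 0.05)
  expect_equal(a$samples, b$samples)
  expect_equal(a$mean_iv, b$mean_iv)
  expect_equal(a$summary, b$summary)
  expect_error(averaging_study(n = 1), "n >= 2")
})

test_that("degenerate sampling bounds at tiny Rs give vanishing bias", {
  prs <- iv_protocols(-100, 20, -40, 10, 10, 10)
  st <- averaging_study(
    n = 2, seed = 1,
    bounds = list(scale = c(1, 1), Rs = c(1e-3, 1e-3), Cm = c(15, 15)),
    protocols = prs, dt_out = 0.02)
  expect_lt(abs(st$summary$peak_underestimation_pct), 2)
  expect_equal(st$summary$peak_shift_mV, 0)
})

test_that("impossible quality control fails after a bounded resample budget", {
  expect_error(
    mutant_drug_study(n_per_arm = 2, seed = 1, qc_Rs_max = 1e-6,
                      max_draws = 25),
    "Quality control")
})

test_that("near-ideal conditions remove the mutant-study shift", {
  st <- mutant_drug_study(
    n_per_arm = 2, seed = 3, qc_Rs_max = 4,
    Rs_dist = c(mean = 0.002, var = 1e-10),
    Cm_dist = c(mean = 40, var = 1e-8),
    voff_var = 1e-12, est_err_sd = 1e-6,
    protocols = iv_protocols(-100, 20, -40, 10, 10, 10), dt_out = 0.02)
  expect_equal(st$summary$observed_shift_mV, 0)
  expect_equal(st$summary$ideal_shift_mV, 0)
})

test_that("the mutant study is deterministic given its master seed", {
  prs <- iv_protocols(-100, 20, -30, -10, 10, 10)
  a <- mutant_drug_study(n_per_arm = 2, seed = 9, protocols = prs,
                         dt_out = 0.05)
  b <- mutant_drug_study(n_per_arm = 2, seed = 9, protocols = prs,
                         dt_out = 0.05)
  expect_equal(a$arms, b$arms)
  expect_equal(a$summary, b$summary)
  # the arms differ only in current density, by the stated factor of three
  expect_equal(unique(a$arms$density), c(1500, 500))
})

test_that("near-threshold peaks are delayed more than suprathreshold peaks", {
  # loss-of-clamp positive feedback: at a command just below threshold the
  # current builds up with a delay; far above threshold it peaks promptly
  ina <- generic_ina(g_max = 1.5)
  s <- ina_settings(0.4, 0.4)
  prs <- iv_protocols(-100, 20, -40, 0, 40, 15)  # two steps: -40 and 0 mV
  art <- simulate_iv(s, ina_cell(), ina, prs, dt_out = 0.01, dt_hold = 2,
                     direction = "inward")
  ide <- simulate_iv(NULL, NULL, ina, prs, ideal = TRUE, dt_out = 0.01,
                     dt_hold = 2, direction = "inward")
  delay <- art$time_to_peak_ms - ide$time_to_peak_ms
  expect_gt(delay[art$voltage_mV == -40], delay[art$voltage_mV == 0])
  expect_gt(delay[art$voltage_mV == -40], 0)
})

test_that("normalising individual curves before averaging does not remove the shift", {
  st <- averaging_study(n = 5, seed = 1)
  normed <- lapply(st$curves, function(cv) {
    cv$peak_current_nA <- cv$peak_current_nA / max(abs(cv$peak_current_nA))
    cv
  })
  mean_norm <- average_iv(normed)
  shift <- iv_peak(st$ideal_iv)$voltage_mV - iv_peak(mean_norm)$voltage_mV
  expect_true(shift != 0)
})
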