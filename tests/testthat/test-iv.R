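test_that("a zero-current trace yields a zero peak at the window start", {
  tr <- tibble::tibble(
    time_ms = seq(0, 30, 0.1), vcmd_mV = 0, vm_mV = 0, vp_mV = 0,
    vclamp_mV = 0, vest_mV = 0, iion_nA = 0, iout_nA = 0, ipost_nA = 0)
  class(tr) <- c("vc_trace", class(tr))
  pr <- step_protocol(-80, 10, 0, 10, 10)
  iv <- compute_iv(list(tr), list(pr), blank_ms = 0.2)
  expect_equal(iv$peak_current_nA, 0)
  expect_equal(iv$time_to_peak_ms, 0.2)  # tie-break: earliest sample wins
})

test_that("peak detection honours the blanking window and direction", {
  t <- seq(0, 30, 0.05)
  # a decaying spike inside the blank, then a real inward peak at 1 ms
  ipost <- -10 * exp(-pmax(t - 10, 0) / 0.02) * (t >= 10) -
    5 * exp(-((t - 11)^2) / 0.1) + 1.5 * exp(-((t - 15)^2) / 0.2)
  tr <- tibble::tibble(time_ms = t, vcmd_mV = 0, vm_mV = 0, vp_mV = 0,
                       vclamp_mV = 0, vest_mV = 0, iion_nA = 0,
                       iout_nA = ipost, ipost_nA = ipost)
  class(tr) <- c("vc_trace", class(tr))
  pr <- step_protocol(-80, 10, 0, 10, 10)
  iv <- compute_iv(list(tr), list(pr), blank_ms = 0.2)
  expect_equal(iv$time_to_peak_ms, 1, tolerance = 0.06)
  expect_equal(iv$peak_current_nA, -5, tolerance = 0.01)
  expect_error(compute_iv(list(tr), list(pr), blank_ms = 50), "window")
  out <- compute_iv(list(tr), list(pr), blank_ms = 0.2,
                    direction = "outward")
  expect_equal(out$peak_current_nA, 1.5, tolerance = 0.01)
  expect_equal(out$time_to_peak_ms, 5, tolerance = 0.06)
})

test_that("model-cell end-of-step current settles at the linear equilibrium", {
  s <- rig_settings(gleak_est = 0.002)
  cl <- rig_cell(gleak = 0.002)
  pr <- step_protocol(-80, 30, 50, 30, 0)
  tr <- simulate_clamp(s, cl, model_cell(), pr, dt_out = 0.05)
  sys <- model_cell_system(s, cl, model_cell())
  eq <- model_cell_equilibrium(sys, 50)
  expect_equal(tr$iout_nA[nrow(tr)], eq[["Iout"]], tolerance = 1e-6)
})

test_that("averaging I-V curves gives pointwise means and the sample SEM", {
  mk <- function(y) {
    iv <- tibble::tibble(voltage_mV = c(-20, 0, 20), peak_current_nA = y,
                         time_to_peak_ms = 1)
    class(iv) <- c("vc_iv", class(iv))
    iv
  }
  a <- mk(c(-1, -4, -2)); b <- mk(c(-3, -6, -2))
  avg <- average_iv(list(a, b))
  expect_equal(avg$peak_current_nA, c(-2, -5, -2))
  expect_equal(average_iv(list(a, a))$sem, rep(0, 3))
  expect_equal(average_iv(list(a, a))$peak_current_nA, a$peak_current_nA)

  # n copies of {-1, +1}: SEM = sd/sqrt(n) with the sample sd
  n <- 6
  pm <- lapply(seq_len(n), function(i) mk(rep(c(-1, 1)[1 + i %% 2], 3)))
  avg2 <- average_iv(pm)
  expect_equal(avg2$sem, rep(sd(rep(c(-1, 1), 3)) / sqrt(n), 3))

  bad <- mk(c(-1, -4, -2)); bad$voltage_mV <- c(-30, 0, 20)
  expect_error(average_iv(list(a, bad)), "voltage grid")
  expect_error(average_iv(list(a)), "length")
})

test_that("iv_peak keeps the sign and resolves ties to the lowest voltage", {
  iv <- tibble::tibble(voltage_mV = c(-30, -10, 10),
                       peak_current_nA = c(-8, -8, 3))
  class(iv) <- c("vc_iv", class(iv))
  expect_equal(iv_peak(iv)$voltage_mV, -30)
  expect_equal(iv_peak(iv)$peak_current_nA, -8)
})
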