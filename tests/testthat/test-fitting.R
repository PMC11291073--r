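make_fit_problem <- function(dt = 0.1, voltages = c(-30, -10),
                             truth = c(g_max = 0.8, Rs = 6, Cm = 18,
                                       Voff = 2, gleak = 0.002)) {
  sett <- amplifier_settings(alpha_R = 0.8, alpha_P = 0.8,
                             Rs_est = 1.05 * truth[["Rs"]],
                             Cm_est = 0.95 * truth[["Cm"]], Cp_est = 4,
                             gleak_est = 1.05 * truth[["gleak"]])
  cellt <- cell_properties(Rs = truth[["Rs"]], Cm = truth[["Cm"]], Cp = 4,
                           gleak = truth[["gleak"]], Voff = truth[["Voff"]])
  prs <- lapply(voltages, function(v) step_protocol(-100, 5, v, 10, 0))
  data <- lapply(prs, function(p) {
    simulate_clamp(sett, cellt, generic_ina(g_max = truth[["g_max"]]), p,
                   dt_out = dt)
  })
  list(truth = truth, settings = sett, protocols = prs, data = data)
}

test_that("the log transform round-trips and rejects non-positive input", {
  expect_equal(fit_transform(0.6, 0.6), 0)
  expect_equal(fit_transform(0.6 * exp(1), 0.6), 1)
  p <- c(0.3, 7, 22)
  p0 <- c(0.6, 6.3, 17.1)
  expect_equal(fit_untransform(fit_transform(p, p0), p0), p)
  expect_error(fit_transform(-1, 2), "positive")
  expect_error(fit_transform(1, 0), "positive")
})

test_that("the objective vanishes at truth and grows under perturbation", {
  prob <- make_fit_problem()
  obj <- clamp_objective(prob$data, prob$protocols, prob$settings,
                         generic_ina(), cell_properties(Cp = 4),
                         dt_out = 0.1)
  f0 <- obj(prob$truth)
  scale <- sum(vapply(prob$data, function(d) sum(d$ipost_nA^2), numeric(1)))
  expect_lt(f0 / scale, 1e-10)

  bump <- prob$truth
  bump[["g_max"]] <- bump[["g_max"]] * 1.1
  expect_gt(obj(bump), f0 + 1)

  # conductance perturbations of +/- 20% are clearly distinguishable
  for (fac in c(0.8, 1.2)) {
    p <- prob$truth
    p[["g_max"]] <- p[["g_max"]] * fac
    expect_gt(obj(p), f0 + 1)
  }

  # the sum over sweeps is order-invariant
  obj_rev <- clamp_objective(rev(prob$data), rev(prob$protocols),
                             prob$settings, generic_ina(),
                             cell_properties(Cp = 4), dt_out = 0.1)
  expect_equal(obj_rev(prob$truth), f0)

  # simulation failure maps to a large finite penalty, not an error
  crazy <- prob$truth
  crazy[["Rs"]] <- -5
  expect_equal(obj(crazy), 1e12)
})

test_that("an optimiser started at the truth converges immediately", {
  prob <- make_fit_problem(voltages = -20)
  obj <- clamp_objective(prob$data, prob$protocols, prob$settings,
                         generic_ina(), cell_properties(Cp = 4),
                         dt_out = 0.1)
  refs <- c(prob$settings$Rs_est, prob$settings$Cm_est,
            prob$settings$gleak_est)
  theta0 <- c(fit_transform(prob$truth[["g_max"]], 0.6),
              fit_transform(prob$truth[["Rs"]], refs[1]),
              fit_transform(prob$truth[["Cm"]], refs[2]),
              prob$truth[["Voff"]] / 10,
              fit_transform(prob$truth[["gleak"]], refs[3]))
  fn <- function(th) obj(c(g_max = fit_untransform(th[1], 0.6),
                           Rs = fit_untransform(th[2], refs[1]),
                           Cm = fit_untransform(th[3], refs[2]),
                           Voff = 10 * th[4],
                           gleak = fit_untransform(th[5], refs[3])))
  withr::with_seed(1, {
    res <- cma_es(fn, theta0, 1e-4, control = list(maxit = 10))
  })
  expect_lt(res$value, 1e-4)
})

test_that("cma_es minimises smooth benchmark objectives", {
  withr::with_seed(2, {
    ros <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
    r <- cma_es(ros, c(-1.2, 1), 0.5)
    expect_equal(r$par, c(1, 1), tolerance = 1e-4)
    sph <- function(x) sum((x - 1:4)^2)
    r2 <- cma_es(sph, rep(0, 4), 0.3)
    expect_equal(r2$par, 1:4, tolerance = 1e-4)
    # box constraints are respected
    r3 <- cma_es(function(x) sum(x^2), c(2, 2), 0.3, lower = 1, upper = 3)
    expect_true(all(r3$par >= 1 - 1e-12))
  })
})

test_that("best-of-restarts never worsens as restarts grow (nested seeds)", {
  prob <- make_fit_problem(voltages = -20)
  run <- function(restarts) {
    fit_clamp(prob$data, prob$protocols, prob$settings, generic_ina(),
              cell_properties(Cp = 4),
              spec = fit_spec(restarts = restarts, maxit = 10,
                              polish = FALSE),
              seed = 4, dt_out = 0.1)
  }
  f1 <- run(1)
  f2 <- run(2)
  expect_lte(f2$value, f1$value)
  # nested: restart 1 is identical in both runs
  expect_equal(f1$restarts$value[1], f2$restarts$value[1])
  expect_error(fit_clamp(prob$data, prob$protocols,
                         amplifier_settings(gleak_est = 0), generic_ina()),
               "gleak_est")
})

test_that("tidy and glance summarise a fit", {
  prob <- make_fit_problem(voltages = -20)
  fit <- fit_clamp(prob$data, prob$protocols, prob$settings, generic_ina(),
                   cell_properties(Cp = 4),
                   spec = fit_spec(restarts = 1, maxit = 5, polish = FALSE),
                   seed = 1, dt_out = 0.1)
  td <- tidy(fit)
  expect_equal(td$term, c("g_max", "Rs", "Cm", "Voff", "gleak"))
  expect_true(is.na(td$transformed[td$term == "Voff"]))
  expect_equal(fit_untransform(td$transformed[1], td$reference[1]),
               td$estimate[1])
  gl <- glance(fit)
  expect_equal(gl$restarts, 1L)
  expect_gte(gl$objective, 0)
})
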