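#' Sweep compensation settings over a grid
#'
#' Simulates the same cell, ionic model and protocol once per compensation
#' setting, for overlaying traces. The three classic grid types are: varying
#' series-resistance compensation at zero supercharging, varying
#' supercharging at fixed series-resistance compensation, and varying both
#' together.
#'
#' @inheritParams simulate_clamp
#' @param alpha_R,alpha_P Numeric vectors of compensation levels, recycled
#'   to a common length; element `i` of each defines grid point `i`.
#' @param ... Passed to [simulate_clamp()].
#' @return A tibble with columns `alpha_R`, `alpha_P` and a list-column
#'   `trace` of `vc_trace` tibbles.
#' @examples
#' \donttest{
#' sw <- compensation_sweep(amplifier_settings(Rs_est = 30, Cm_est = 22),
#'                          cell_properties(Rs = 30, Cm = 22), model_cell(),
#'                          step_protocol(), alpha_R = c(0, 0.4, 0.8),
#'                          alpha_P = 0, dt_out = 0.05)
#' }
#' @export
compensation_sweep <- function(settings, cell, model, protocol,
                               alpha_R = c(0, 0.2, 0.4, 0.6, 0.8, 0.95),
                               alpha_P = 0, ...) {
  n <- max(length(alpha_R), length(alpha_P))
  alpha_R <- rep_len(alpha_R, n)
  alpha_P <- rep_len(alpha_P, n)
  stopifnot(all(alpha_R >= 0 & alpha_R <= 0.95),
            all(alpha_P >= 0 & alpha_P <= 0.95))
  traces <- purrr::map2(alpha_R, alpha_P, function(ar, ap) {
    s <- settings
    s$alpha_R <- ar
    s$alpha_P <- ap
    simulate_clamp(s, cell, model, protocol, ...)
  })
  out <- tibble::tibble(alpha_R = alpha_R, alpha_P = alpha_P, trace = traces)
  class(out) <- c("vc_sweep", class(out))
  out
}

#' Log-normal sampler parameterised by mean and variance
#'
#' Draws from a log-normal distribution specified by its *own* mean and
#' variance (not those of the underlying normal): the underlying parameters
#' are `mu_N = log(m^2 / sqrt(v + m^2))` and `sigma_N^2 = log(1 + v / m^2)`.
#'
#' @param n Number of draws.
#' @param mean,var Mean and variance of the log-normal distribution.
#' @return Numeric vector of `n` positive draws.
#' @export
rlnorm_meanvar <- function(n, mean, var) {
  stopifnot(mean > 0, var >= 0)
  sdlog2 <- log(1 + var / mean^2)
  stats::rlnorm(n, meanlog = log(mean^2 / sqrt(var + mean^2)),
                sdlog = sqrt(sdlog2))
}

#' I-V averaging bias study
#'
#' Quantifies the systematic bias left by averaging compensated I-V curves
#' across a virtual cell population. Cells are drawn by Latin hypercube:
#' conductance scale log-uniform in `bounds$scale`, series resistance
#' uniform in `bounds$Rs` (MOhm) and membrane capacitance uniform in
#' `bounds$Cm` (pF), with the machine estimates assumed perfect
#' (`Rs_est = Rs`, `Cm_est = Cm`). Each cell's I-V curve is simulated at
#' compensation level `alpha` for both series-resistance compensation and
#' supercharging; the pointwise mean (with SEM) is compared against the
#' artefact-free, baseline-conductance ideal-clamp curve.
#'
#' The bias summary reports the relative underestimation of the
#' largest-magnitude peak, `100 * (1 - |peak(mean IV)| / |peak(ideal IV)|)`,
#' and the leftward shift of the peak voltage, `V_peak(ideal) -
#' V_peak(mean)` in mV.
#'
#' @param n Number of virtual cells (>= 2, for the SEM).
#' @param seed Integer seed; all sampling flows from it.
#' @param alpha Compensation level applied to both `alpha_R` and `alpha_P`.
#' @param model Baseline ionic model (a [generic_ina()]); the conductance
#'   scale multiplies its `g_max`. When `NULL` (the default) the baseline
#'   conductance is derived from `baseline_density` at the midpoint of the
#'   `Cm` bounds, so the scale-1 cell carries a typical fast-sodium current
#'   density.
#' @param baseline_density Ideal-clamp current density (A/F) defining the
#'   baseline conductance when `model` is `NULL`; the default matches the
#'   wild-type density used in [mutant_drug_study()].
#' @param bounds List with elements `scale`, `Rs`, `Cm`, each a length-2
#'   numeric range.
#' @param protocols I-V protocol family; the default holds at -100 mV for
#'   2000 ms then steps for 20 ms through -90..+50 mV in 10 mV increments.
#' @param Cp Pipette capacitance given to every virtual cell (pF), with a
#'   perfect machine estimate.
#' @param dt_out,dt_hold Output sampling (ms) for the test step and the
#'   holding segment.
#' @return An object of class `vc_averaging_study`: a list with `samples`
#'   (tibble of cell parameters), `curves` (list of `vc_iv`), `mean_iv`,
#'   `ideal_iv`, and `summary` (one-row tibble with
#'   `peak_underestimation_pct`, `peak_shift_mV`, `n`, `seed`).
#' @export
averaging_study <- function(n = 75, seed = 1, alpha = 0.8,
                            model = NULL, baseline_density = 1500,
                            bounds = list(scale = c(0.2, 5), Rs = c(4, 15),
                                          Cm = c(8, 22)),
                            protocols = iv_protocols(), Cp = 4,
                            dt_out = 0.01, dt_hold = 5) {
  if (is.null(model)) {
    model <- generic_ina()
    model$g_max <- density_to_conductance(baseline_density, mean(bounds$Cm),
                                          model, protocols, dt_out = dt_out)
  }
  stopifnot(n >= 2, inherits(model, "vc_hh_ina"),
            all(vapply(bounds, length, integer(1)) == 2),
            all(unlist(bounds) > 0))
  set.seed(seed)
  u <- lhs::randomLHS(n, 3)
  samples <- tibble::tibble(
    cell = seq_len(n),
    conductance_scale = exp(log(bounds$scale[1]) +
                              u[, 1] * diff(log(bounds$scale))),
    Rs = bounds$Rs[1] + u[, 2] * diff(bounds$Rs),
    Cm = bounds$Cm[1] + u[, 3] * diff(bounds$Cm)
  )
  curves <- purrr::pmap(samples[-1], function(conductance_scale, Rs, Cm) {
    m <- model
    m$g_max <- model$g_max * conductance_scale
    cellp <- cell_properties(Rs = Rs, Cm = Cm, Cp = Cp)
    sett <- amplifier_settings(alpha_R = alpha, alpha_P = alpha,
                               Rs_est = Rs, Cm_est = Cm, Cp_est = Cp)
    simulate_iv(sett, cellp, m, protocols, dt_out = dt_out,
                dt_hold = dt_hold, direction = "inward")
  })
  mean_iv <- average_iv(curves)
  ideal_iv <- simulate_iv(NULL, NULL, model, protocols, ideal = TRUE,
                          dt_out = dt_out, dt_hold = dt_hold,
                          direction = "inward")
  structure(
    list(samples = samples, curves = curves, mean_iv = mean_iv,
         ideal_iv = ideal_iv,
         summary = iv_bias_summary(mean_iv, ideal_iv, n = n, seed = seed),
         alpha = alpha, seed = seed),
    class = "vc_averaging_study"
  )
}

# Peak-current underestimation and peak-voltage left shift of an observed
# mean I-V relative to the artefact-free reference.
iv_bias_summary <- function(observed_iv, ideal_iv, n = NA_integer_,
                            seed = NA_integer_) {
  po <- iv_peak(observed_iv)
  pi <- iv_peak(ideal_iv)
  tibble::tibble(
    peak_underestimation_pct =
      100 * (1 - abs(po$peak_current_nA) / abs(pi$peak_current_nA)),
    peak_shift_mV = pi$voltage_mV - po$voltage_mV,
    n = n, seed = seed
  )
}

#' Virtual mutant/drug mischaracterisation study
#'
#' Simulates the patch-clamp characterisation of a variant (or drugged)
#' channel whose *only* true effect is a reduced current density, and asks
#' what the recorded mean I-V curves suggest instead. Each arm draws virtual
#' cells with `Rs ~ LogNormal(mean 2.5, var 1.5)` MOhm, `Cm ~ LogNormal(mean
#' 40, var 10)` pF and residual offset `Voff ~ Normal(0, var 2.5)` mV; cells
#' failing the quality-control criterion `Rs < qc_Rs_max` are redrawn (with a
#' bounded budget) so each arm keeps exactly `n_per_arm` accepted cells. The
#' machine estimates carry 5% multiplicative error: `Rs_est = N(1, sd
#' est_err_sd) * Rs` and likewise for `Cm_est`. Conductance is scaled from
#' the arm's current density via [density_to_conductance()] using each
#' cell's sampled `Cm`, so all cells share the same ideal-clamp density.
#'
#' @param n_per_arm Accepted cells per arm.
#' @param seed Integer master seed.
#' @param qc_Rs_max Quality-control ceiling on series resistance (MOhm).
#' @param alpha Compensation level for both compensation pathways.
#' @param densities Named or unnamed length-2 vector of current densities
#'   (A/F): control/WT first, mutant/drug second.
#' @param model Baseline ionic model (gating is shared; conductance is set
#'   per cell).
#' @param protocols I-V protocol family (default as in [averaging_study()]).
#' @param Rs_dist,Cm_dist Length-2 `(mean, variance)` of the log-normal cell
#'   distributions.
#' @param voff_var Variance of the normal residual-offset distribution
#'   (mV^2).
#' @param est_err_sd Standard deviation of the multiplicative estimation
#'   error on `Rs_est` and `Cm_est`.
#' @param Cp Pipette capacitance (pF), perfectly estimated.
#' @param dt_out,dt_hold Output sampling (ms).
#' @param max_draws Resampling budget per arm before giving up on QC.
#' @return An object of class `vc_mutant_study`: a list with `arms` (tibble
#'   of per-cell parameters and arm labels), `curves` (per-arm lists of
#'   `vc_iv`), `mean_ivs`, `ideal_ivs`, and `summary` (observed and ideal
#'   peak-voltage difference between arms, mV).
#' @export
mutant_drug_study <- function(n_per_arm = 15, seed = 1, qc_Rs_max = 4,
                              alpha = 0.8,
                              densities = c(control = 1500, mutant = 500),
                              model = generic_ina(),
                              protocols = iv_protocols(),
                              Rs_dist = c(mean = 2.5, var = 1.5),
                              Cm_dist = c(mean = 40, var = 10),
                              voff_var = 2.5, est_err_sd = 0.05,
                              Cp = 4, dt_out = 0.01, dt_hold = 5,
                              max_draws = 1000) {
  stopifnot(n_per_arm >= 1, length(densities) == 2, all(densities > 0),
            qc_Rs_max > 0)
  if (is.null(names(densities))) names(densities) <- c("control", "mutant")
  set.seed(seed)
  peak_unit <- unit_peak_current(model, protocols, dt_out = dt_out)

  draw_arm <- function(arm, density) {
    rs <- numeric(0)
    draws <- 0
    while (length(rs) < n_per_arm) {
      if (draws >= max_draws) {
        stop("Quality control Rs < ", qc_Rs_max, " MOhm rejected all of ",
             max_draws, " draws; threshold below the distribution support?",
             call. = FALSE)
      }
      cand <- rlnorm_meanvar(1, Rs_dist[["mean"]], Rs_dist[["var"]])
      draws <- draws + 1
      if (cand < qc_Rs_max) rs <- c(rs, cand)
    }
    tibble::tibble(
      arm = arm, cell = seq_len(n_per_arm), density = density,
      Rs = rs,
      Cm = rlnorm_meanvar(n_per_arm, Cm_dist[["mean"]], Cm_dist[["var"]]),
      Voff = stats::rnorm(n_per_arm, 0, sqrt(voff_var)),
      Rs_est = stats::rnorm(n_per_arm, 1, est_err_sd) * rs,
      Cm_est = NA_real_, g_max = NA_real_
    ) |>
      dplyr::mutate(
        Cm_est = stats::rnorm(n_per_arm, 1, est_err_sd) * .data$Cm,
        g_max = .data$density * .data$Cm * 1e-3 / peak_unit
      )
  }
  arms <- dplyr::bind_rows(
    draw_arm(names(densities)[1], densities[[1]]),
    draw_arm(names(densities)[2], densities[[2]])
  )

  curves <- lapply(split(arms, arms$arm), function(df) {
    purrr::pmap(
      df[c("Rs", "Cm", "Voff", "Rs_est", "Cm_est", "g_max")],
      function(Rs, Cm, Voff, Rs_est, Cm_est, g_max) {
        m <- model
        m$g_max <- g_max
        cellp <- cell_properties(Rs = Rs, Cm = Cm, Cp = Cp, Voff = Voff)
        sett <- amplifier_settings(alpha_R = alpha, alpha_P = alpha,
                                   Rs_est = Rs_est, Cm_est = Cm_est,
                                   Cp_est = Cp)
        simulate_iv(sett, cellp, m, protocols, dt_out = dt_out,
                    dt_hold = dt_hold, direction = "inward")
      })
  })[unique(arms$arm)]
  mean_ivs <- lapply(curves, average_iv)

  ideal_ivs <- lapply(stats::setNames(as.numeric(densities),
                                      names(densities)), function(d) {
    m <- model
    m$g_max <- d * Cm_dist[["mean"]] * 1e-3 / peak_unit
    simulate_iv(NULL, NULL, m, protocols, ideal = TRUE, dt_out = dt_out,
                dt_hold = dt_hold, direction = "inward")
  })

  obs_peaks <- vapply(mean_ivs, function(iv) iv_peak(iv)$voltage_mV,
                      numeric(1))
  ideal_peaks <- vapply(ideal_ivs, function(iv) iv_peak(iv)$voltage_mV,
                        numeric(1))
  structure(
    list(arms = arms, curves = curves, mean_ivs = mean_ivs,
         ideal_ivs = ideal_ivs,
         summary = tibble::tibble(
           observed_shift_mV = unname(abs(obs_peaks[1] - obs_peaks[2])),
           ideal_shift_mV = unname(abs(ideal_peaks[1] - ideal_peaks[2])),
           n_per_arm = n_per_arm, seed = seed
         ),
         alpha = alpha, seed = seed),
    class = "vc_mutant_study"
  )
}

#' @export
print.vc_averaging_study <- function(x, ...) {
  cat("<I-V averaging bias study>\n")
  cat(sprintf("  n = %d cells, alpha = %.0f%%, seed = %d\n",
              x$summary$n, 100 * x$alpha, x$seed))
  cat(sprintf("  peak underestimation: %.1f%%; peak left shift: %g mV\n",
              x$summary$peak_underestimation_pct, x$summary$peak_shift_mV))
  invisible(x)
}

#' @export
print.vc_mutant_study <- function(x, ...) {
  cat("<virtual mutant/drug study>\n")
  cat(sprintf("  n = %d per arm, alpha = %.0f%%, seed = %d\n",
              x$summary$n_per_arm, 100 * x$alpha, x$seed))
  cat(sprintf("  observed peak-voltage shift: %g mV (ideal: %g mV)\n",
              x$summary$observed_shift_mV, x$summary$ideal_shift_mV))
  invisible(x)
}
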