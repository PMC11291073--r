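#' Specification of a clamp-model fit
#'
#' Declares the free parameters and optimiser settings for fitting the
#' coupled cell-amplifier model to recorded current traces. The free
#' parameters are the ionic maximal conductance and the instrument-side cell
#' parameters: `Rs`, `Cm`, `Voff` and `gleak`. Conductance, `Rs`, `Cm` and
#' `gleak` are positive and are searched on a log scale, `p = p0 * exp(s)`,
#' each relative to a reference `p0`: a fixed conductance reference
#' (`g0`, default 0.6 uS = 600 nS) and the machine estimates `Rs_est`,
#' `Cm_est`, `gleak_est` for the rest. The signed offset `Voff` is searched
#' untransformed.
#'
#' @param g0 Reference conductance (uS) for the log transform.
#' @param restarts Number of random restarts of the optimiser.
#' @param s_bounds Length-2 range of the transformed coordinates from which
#'   starting points are drawn (also a soft search box, widened by
#'   `box_factor`).
#' @param voff_bounds Length-2 range (mV) for `Voff` starting points.
#' @param box_factor Hard search box = `box_factor * s_bounds`.
#' @param maxit Generation limit per restart of [cma_es()].
#' @param sigma0 Initial CMA-ES step size in transformed coordinates.
#' @param polish Run a final Nelder-Mead refinement from the best restart?
#' @return An object of class `vc_fit_spec`.
#' @export
fit_spec <- function(g0 = 0.6, restarts = 40, s_bounds = c(-2, 2),
                     voff_bounds = c(-20, 20), box_factor = 3,
                     maxit = 300, sigma0 = 0.5, polish = TRUE) {
  stopifnot(g0 > 0, restarts >= 1, length(s_bounds) == 2,
            length(voff_bounds) == 2, sigma0 > 0)
  structure(list(g0 = g0, restarts = restarts, s_bounds = sort(s_bounds),
                 voff_bounds = sort(voff_bounds), box_factor = box_factor,
                 maxit = maxit, sigma0 = sigma0, polish = polish),
            class = "vc_fit_spec")
}

#' Log transform of positive fit parameters
#'
#' `fit_transform()` maps a positive parameter to its search coordinate
#' `s = log(p / p0)`; `fit_untransform()` inverts it, `p = p0 * exp(s)`.
#' The round trip is exact to machine precision. The voltage offset is
#' searched untransformed (it may be negative) and does not pass through
#' these functions.
#'
#' @param p,p0 Positive parameter value(s) and reference value(s).
#' @param s Transformed coordinate(s).
#' @return The transformed (`fit_transform`) or natural (`fit_untransform`)
#'   parameter value(s).
#' @examples
#' fit_transform(0.6 * exp(1), 0.6)   # 1
#' fit_untransform(0, 12)             # the reference itself
#' @export
fit_transform <- function(p, p0) {
  if (any(p <= 0) || any(p0 <= 0)) {
    stop("Log-transformed parameters and their references must be positive.",
         call. = FALSE)
  }
  log(p / p0)
}

#' @rdname fit_transform
#' @export
fit_untransform <- function(s, p0) p0 * exp(s)

#' Sum-of-squares objective for clamp-model fitting
#'
#' Builds the objective function used by [fit_clamp()]: for a proposed
#' parameter set, simulate every sweep with the artefact model, interpolate
#' the simulated post-processed current onto the data's time points, and
#' return the unweighted sum of squared residuals over all sweeps and time
#' points. Simulation failures at pathological parameter proposals return a
#' large finite penalty so that the optimiser can continue.
#'
#' @param data List of observed traces (tibbles with `time_ms` and
#'   `ipost_nA`), one per protocol sweep.
#' @param protocols Matching list of `vc_protocol` objects; defaults to the
#'   protocols embedded in `data`.
#' @param settings [amplifier_settings()] used during the recording
#'   (compensation levels and machine estimates are fixed, known inputs).
#' @param model Ionic model whose `g_max` is replaced per proposal.
#' @param cell_template [cell_properties()] supplying the fixed `Cp` and
#'   `Eleak`; `Rs`, `Cm`, `Voff`, `gleak` are replaced per proposal.
#' @param dt_out Simulation output interval (ms) before interpolation onto
#'   the data grid.
#' @return A function `f(params)` taking a named vector
#'   `(g_max, Rs, Cm, Voff, gleak)` and returning the scalar objective.
#' @export
clamp_objective <- function(data, protocols = NULL, settings, model,
                            cell_template = cell_properties(),
                            dt_out = 0.05) {
  protocols <- protocols %||% lapply(data, attr, "protocol")
  stopifnot(length(data) >= 1, length(data) == length(protocols))
  force(settings); force(model); force(cell_template)
  function(params) {
    params <- as.list(params)
    m <- model
    m$g_max <- params$g_max
    cellp <- tryCatch(
      cell_properties(Rs = params$Rs, Cm = params$Cm,
                      Cp = cell_template$Cp, gleak = params$gleak,
                      Eleak = cell_template$Eleak, Voff = params$Voff),
      error = function(e) NULL
    )
    if (is.null(cellp)) return(1e12)
    sse <- 0
    for (i in seq_along(data)) {
      sim <- tryCatch(
        suppressWarnings(
          simulate_clamp(settings, cellp, m, protocols[[i]],
                         dt_out = dt_out, dt_hold = max(dt_out, 1))),
        error = function(e) NULL
      )
      if (is.null(sim)) return(1e12)
      pred <- interp_by_segment(sim, data[[i]]$time_ms, protocols[[i]])
      sse <- sse + sum((pred - data[[i]]$ipost_nA)^2)
    }
    sse
  }
}

# Interpolate a simulated trace onto data time points without smearing the
# discontinuities at protocol segment boundaries (the leak-subtracted
# current jumps with the command).
interp_by_segment <- function(sim, t_out, protocol) {
  ends <- cumsum(protocol$duration_ms)
  starts <- c(0, ends[-length(ends)])
  out <- rep(NA_real_, length(t_out))
  for (k in seq_along(starts)) {
    last <- k == length(starts)
    sel_d <- t_out >= starts[k] & (if (last) t_out <= ends[k] else
      t_out < ends[k])
    sel_s <- sim$time_ms >= starts[k] & (if (last) sim$time_ms <= ends[k] else
      sim$time_ms < ends[k])
    if (!any(sel_d)) next
    out[sel_d] <- stats::approx(sim$time_ms[sel_s], sim$ipost_nA[sel_s],
                                xout = t_out[sel_d], rule = 2, ties = "ordered")$y
  }
  out
}

#' Fit the clamp model to recorded current traces
#'
#' Multi-restart derivative-free fitting of the coupled cell-amplifier
#' model: the ionic maximal conductance and the cell-side parameters `Rs`,
#' `Cm`, `Voff`, `gleak` are adjusted so the simulated post-processed
#' current reproduces the observed sweeps, with the amplifier's compensation
#' levels and machine estimates held at their known values. Positive
#' parameters are searched as `p = p0 * exp(s)` (see [fit_transform()]);
#' each restart draws a fresh starting point in transformed space and runs
#' [cma_es()]; the best restart optionally gets a Nelder-Mead polish.
#' Deterministic for a given `seed`.
#'
#' @inheritParams clamp_objective
#' @param spec A [fit_spec()].
#' @param seed Integer master seed controlling all restarts.
#' @return An object of class `vc_fit`: a list with `par` (named vector of
#'   fitted parameters on the natural scale), `value` (objective at the
#'   optimum), `reference` (the `p0` values), `restarts` (per-restart tibble
#'   with seed, start, final value, convergence), and `spec`.
#' @export
fit_clamp <- function(data, protocols = NULL, settings, model,
                      cell_template = cell_properties(),
                      spec = fit_spec(), seed = 1, dt_out = 0.05) {
  stopifnot(inherits(spec, "vc_fit_spec"))
  refs <- c(g_max = spec$g0, Rs = settings$Rs_est, Cm = settings$Cm_est,
            gleak = settings$gleak_est)
  if (refs[["gleak"]] <= 0) {
    stop("Fitting `gleak` requires a positive `gleak_est` reference in the ",
         "amplifier settings.", call. = FALSE)
  }
  obj <- clamp_objective(data, protocols, settings, model, cell_template,
                         dt_out = dt_out)
  # search coordinates: (s_g, s_Rs, s_Cm, Voff/10, s_gleak)
  to_natural <- function(theta) {
    c(g_max = fit_untransform(theta[1], refs[["g_max"]]),
      Rs = fit_untransform(theta[2], refs[["Rs"]]),
      Cm = fit_untransform(theta[3], refs[["Cm"]]),
      Voff = 10 * theta[4],
      gleak = fit_untransform(theta[5], refs[["gleak"]]))
  }
  fn <- function(theta) obj(to_natural(theta))

  box <- spec$box_factor * max(abs(spec$s_bounds))
  lower <- c(rep(-box, 3), spec$voff_bounds[1] / 10 * spec$box_factor, -box)
  upper <- c(rep(box, 3), spec$voff_bounds[2] / 10 * spec$box_factor, box)

  rows <- vector("list", spec$restarts)
  best <- NULL
  for (r in seq_len(spec$restarts)) {
    rseed <- seed * 1000L + r
    set.seed(rseed)
    theta0 <- c(stats::runif(3, spec$s_bounds[1], spec$s_bounds[2]),
                stats::runif(1, spec$voff_bounds[1], spec$voff_bounds[2]) / 10,
                stats::runif(1, spec$s_bounds[1], spec$s_bounds[2]))
    res <- cma_es(fn, theta0, spec$sigma0, lower = lower, upper = upper,
                  control = list(maxit = spec$maxit))
    rows[[r]] <- tibble::tibble(
      restart = r, seed = rseed, value = res$value, evals = res$counts,
      generations = res$generations, converged = res$convergence == 0L,
      start = list(theta0), par = list(res$par)
    )
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("All restarts failed; see the per-restart table for diagnostics.",
         call. = FALSE)
  }
  if (spec$polish) {
    pol <- stats::optim(best$par, fn, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-14))
    if (pol$value <= best$value) {
      best$par <- pol$par
      best$value <- pol$value
    }
  }
  structure(
    list(par = to_natural(best$par), value = best$value,
         reference = c(refs, Voff = 0),
         restarts = dplyr::bind_rows(rows), spec = spec, seed = seed,
         settings = settings),
    class = "vc_fit"
  )
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("<clamp-model fit>\n")
  cat(sprintf("  objective %.6g after %d restart(s)\n", x$value,
              nrow(x$restarts)))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted parameters of a clamp-model fit
#'
#' @param x A `vc_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter: `term`, `estimate`,
#'   `reference` (the transform's `p0`; 0 for the untransformed offset) and
#'   `transformed` (the search coordinate `s`, `NA` for the offset).
#' @export
tidy.vc_fit <- function(x, ...) {
  terms <- names(x$par)
  ref <- x$reference[terms]
  s <- rep(NA_real_, length(terms))
  pos <- terms != "Voff"
  s[pos] <- log(unname(x$par[pos]) / unname(ref[pos]))
  tibble::tibble(
    term = terms,
    estimate = unname(x$par),
    reference = unname(ref),
    transformed = s
  )
}

#' One-row summary of a clamp-model fit
#'
#' @param x A `vc_fit` object.
#' @param ... Unused.
#' @return A tibble with the objective value, restart count, total function
#'   evaluations, and whether the best restart converged.
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$value,
    restarts = nrow(x$restarts),
    evals = sum(x$restarts$evals),
    best_converged = x$restarts$converged[which.min(x$restarts$value)]
  )
}
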