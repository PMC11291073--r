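#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' A self-contained implementation of the standard (mu/mu_w, lambda) CMA-ES
#' with cumulative step-size adaptation and rank-one plus rank-mu covariance
#' updates, following the canonical parameterisation of the strategy
#' constants. Derivative-free and invariant to monotone transformations of
#' the objective; suited to the noiseless, moderately ill-conditioned
#' objectives that arise when fitting the clamp model.
#'
#' @param fn Objective function of a numeric vector, returning a scalar to
#'   minimise. Non-finite returns are treated as very large.
#' @param x0 Numeric start vector (mean of the initial search distribution).
#' @param sigma0 Initial step size (in the units of `x0`).
#' @param lower,upper Optional box bounds (recycled); candidates are clamped
#'   to the box before evaluation.
#' @param control List of options: `maxit` (generations, default
#'   `200 * n`), `popsize` (lambda, default `4 + floor(3 log n)`),
#'   `stop_fitness_tol` (spread of the population's objective values below
#'   which to stop, default 1e-12), `stop_sigma` (minimum step size,
#'   default 1e-12), `trace` (print progress every so many generations, 0 =
#'   silent).
#' @return A list with `par`, `value`, `counts` (function evaluations),
#'   `generations`, and `convergence` (0 = tolerance met, 1 = iteration
#'   limit).
#' @examples
#' f <- function(x) sum((x - 1:3)^2)
#' cma_es(f, c(0, 0, 0), 0.5)$par
#' @export
cma_es <- function(fn, x0, sigma0, lower = -Inf, upper = Inf,
                   control = list()) {
  n <- length(x0)
  stopifnot(n >= 1, sigma0 > 0)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)

  lambda <- control$popsize %||% (4L + floor(3 * log(n)))
  maxit <- control$maxit %||% (200L * n)
  ftol <- control$stop_fitness_tol %||% 1e-12
  sigma_min <- control$stop_sigma %||% 1e-12
  trace_every <- control$trace %||% 0

  mu <- floor(lambda / 2)
  w <- log((lambda + 1) / 2) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)

  cc <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
  cs <- (mu_eff + 2) / (n + mu_eff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mu_eff)
  cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
  damps <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + cs
  chi_n <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- as.numeric(x0)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n)
  eigen_stale <- TRUE
  B <- diag(n)
  D <- rep(1, n)
  best_x <- xmean
  best_f <- Inf
  evals <- 0L

  for (gen in seq_len(maxit)) {
    if (eigen_stale) {
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      B <- eg$vectors
      D <- sqrt(pmax(eg$values, .Machine$double.eps))
      eigen_stale <- FALSE
    }
    z <- matrix(stats::rnorm(n * lambda), n, lambda)
    y <- B %*% (D * z)
    x <- xmean + sigma * y
    x <- pmin(pmax(x, lower), upper)
    f <- apply(x, 2, function(xi) {
      v <- fn(xi)
      if (!is.finite(v)) v <- 1e300
      v
    })
    evals <- evals + lambda
    ord <- order(f)
    if (f[ord[1]] < best_f) {
      best_f <- f[ord[1]]
      best_x <- x[, ord[1]]
    }

    sel <- ord[seq_len(mu)]
    # recompute selected steps from clamped candidates so bounds stay honest
    ysel <- (x[, sel, drop = FALSE] - xmean) / sigma
    ymean <- as.numeric(ysel %*% w)
    xmean <- xmean + sigma * ymean

    # step-size path (in the isotropic coordinate system)
    Cinv_half_y <- B %*% ((1 / D) * crossprod(B, ymean))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mu_eff) * Cinv_half_y
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chi_n <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mu_eff) * ymean

    rank_mu <- ysel %*% (w * t(ysel))
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * rank_mu
    eigen_stale <- TRUE
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chi_n - 1))

    if (trace_every > 0 && gen %% trace_every == 0) {
      message(sprintf("cma_es: gen %d  f = %.6g  sigma = %.3g",
                      gen, best_f, sigma))
    }
    if (diff(range(f)) < ftol || sigma < sigma_min) {
      return(list(par = best_x, value = best_f, counts = evals,
                  generations = gen, convergence = 0L))
    }
  }
  list(par = best_x, value = best_f, counts = evals, generations = maxit,
       convergence = 1L)
}
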