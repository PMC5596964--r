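#' Fit the two-state denaturation model to a titration curve
#'
#' Least-squares fit of the two-state model with sloping baselines to an
#' equilibrium titration, by Levenberg-Marquardt with multi-start
#' initialisation. Baselines are initialised by ordinary linear fits to
#' the first and last 20% of points; the (m, D50) start is taken from a
#' small grid (m in 0.3/0.8/1.5/2.5 kcal/mol/M, D50 at the quartiles of
#' the concentration range) unless an explicit `init` is supplied.
#'
#' Standard errors come from the local curvature of the objective (the
#' Jacobian cross-product at the optimum); `se(dG)` is propagated from
#' `se(m)` and `se(D50)` to first order. The fit is invariant to affine
#' rescaling of the signal axis: baselines transform accordingly while
#' `m` and `D50` are unchanged.
#'
#' @param curve A [titration_curve()].
#' @param init Optional [two_state_fit()] used as the single start.
#' @param rt Thermal energy RT in kcal/mol.
#' @param control List with `tol` (relative SSE convergence tolerance,
#'   default 1e-10) and `maxiter` (default 500).
#' @return A [two_state_fit()] with `se` populated and attributes
#'   `residual_sse` and `n`.
#' @export
fit_two_state <- function(curve, init = NULL, rt = .RT,
                          control = list(tol = 1e-10, maxiter = 500)) {
  stopifnot(inherits(curve, "titration_curve"))
  x <- curve$denaturant; y <- curve$signal
  if (length(x) < 8L) stop("at least 8 titration points are required")
  if (diff(range(y)) <= 0) stop("signal has no dynamic range")

  resid_fun <- function(par) {
    fit <- list(a_N = par[1], b_N = par[2], a_D = par[3], b_D = par[4],
                m = exp(par[5]), D50 = exp(par[6]))
    y - eval_two_state_titration(x, fit, rt)
  }

  starts <- if (!is.null(init)) {
    list(c(init$a_N, init$b_N, init$a_D, init$b_D,
           log(init$m), log(init$D50)))
  } else {
    n <- length(x)
    head_i <- seq_len(max(2L, floor(0.2 * n)))
    tail_i <- seq(n - max(2L, floor(0.2 * n)) + 1L, n)
    cf_n <- stats::coef(stats::lm(y[head_i] ~ x[head_i]))
    cf_d <- stats::coef(stats::lm(y[tail_i] ~ x[tail_i]))
    d50_grid <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    d50_grid <- d50_grid[d50_grid > 0]
    starts <- list()
    for (m0 in c(0.3, 0.8, 1.5, 2.5))
      for (d0 in d50_grid)
        starts[[length(starts) + 1L]] <-
          c(cf_n[1], cf_n[2], cf_d[1], cf_d[2], log(m0), log(d0))
    starts
  }

  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           ftol = control$tol, ptol = 1e-12, gtol = 0,
                           maxiter = control$maxiter)),
      error = function(e) NULL)
    if (is.null(res)) next
    sse <- sum(res$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = res, sse = sse)
  }
  if (is.null(best)) stop("two-state fit failed to converge from any start")

  par <- best$fit$par
  m <- exp(par[5]); D50 <- exp(par[6])
  if (D50 < min(x) || D50 > max(x))
    stop("no transition detected: fitted midpoint ", sprintf("%.2f", D50),
         " M lies outside the sampled range [", sprintf("%.2f", min(x)),
         ", ", sprintf("%.2f", max(x)), "] M")

  # covariance from the Jacobian at the optimum (parameters on the
  # internal scale: log m, log D50), then delta method back
  np <- 6L; n <- length(x)
  se <- rep(NA_real_, np)
  cov_try <- tryCatch({
    J <- best$fit$hessian  # nls.lm returns J'J (deviance hessian / 2)
    sigma2 <- best$sse / max(n - np, 1L)
    diag(solve(J) * sigma2)
  }, error = function(e) rep(NA_real_, np))
  if (all(is.finite(cov_try)) && all(cov_try >= 0)) se <- sqrt(cov_try)
  se_m <- m * se[5]; se_D50 <- D50 * se[6]
  se_dG <- sqrt((D50 * se_m)^2 + (m * se_D50)^2)
  out <- two_state_fit(par[1], par[2], par[3], par[4], m, D50,
                       se = c(a_N = se[1], b_N = se[2], a_D = se[3],
                              b_D = se[4], m = se_m, D50 = se_D50,
                              dG = se_dG))
  attr(out, "residual_sse") <- best$sse
  attr(out, "n") <- n
  out
}

#' Bootstrap standard errors for a two-state fit
#'
#' Residual-resampling bootstrap: residuals of the converged fit are
#' resampled with replacement, added back to the fitted values, and the
#' model refitted (from the original optimum). The per-parameter standard
#' deviation over the refits is returned.
#'
#' @param curve The fitted [titration_curve()].
#' @param fit The converged [two_state_fit()].
#' @param n_boot Number of bootstrap replicates; fewer than 50 sets a
#'   `"low_n_boot"` flag on the result.
#' @param seed RNG seed; results are deterministic given the seed.
#' @param rt Thermal energy RT in kcal/mol.
#' @return Named numeric of bootstrap standard errors for a_N, b_N, a_D,
#'   b_D, m, D50 and dG, with attribute `flags`.
#' @export
bootstrap_errors <- function(curve, fit, n_boot = 200, seed = 0, rt = .RT) {
  stopifnot(inherits(curve, "titration_curve"), inherits(fit, "two_state_fit"))
  flags <- character()
  if (n_boot < 50) flags <- c(flags, "low_n_boot")
  yhat <- eval_two_state_titration(curve$denaturant, fit, rt)
  res <- curve$signal - yhat
  n <- length(res)
  draws <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      yb <- yhat + sample(res, n, replace = TRUE)
      cb <- titration_curve(curve$denaturant, yb, label = curve$label)
      fb <- tryCatch(fit_two_state(cb, init = fit, rt = rt),
                     error = function(e) NULL)
      if (is.null(fb)) return(rep(NA_real_, 7L))
      c(fb$a_N, fb$b_N, fb$a_D, fb$b_D, fb$m, fb$D50, fb$dG)
    }, numeric(7L)))
  })
  se <- apply(draws, 2, stats::sd, na.rm = TRUE)
  names(se) <- c("a_N", "b_N", "a_D", "b_D", "m", "D50", "dG")
  attr(se, "flags") <- flags
  se
}
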