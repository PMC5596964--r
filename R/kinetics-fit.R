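# Linear solve of (offset, amplitudes) for fixed decay rates; amplitudes
# are defined at t = 0, so the basis uses absolute time.
.exp_linear_solve <- function(t, y, rates) {
  X <- cbind(1, vapply(rates, function(k) exp(-k * t), numeric(length(t))))
  cf <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) NULL)
  if (is.null(cf) || any(!is.finite(cf))) return(NULL)
  resid <- y - drop(X %*% cf)
  list(offset = cf[1], amplitudes = cf[-1], sse = sum(resid^2))
}

#' Fit a mono- or bi-exponential relaxation to a stopped-flow trace
#'
#' Least-squares fit of `offset + sum_i A_i exp(-k_i t)` to the trace
#' signal over `t >= dead_time` (points inside the dead time are
#' excluded). Amplitudes are reported as extrapolated to t = 0, the
#' moment of mixing. Rates are initialised from a log-spaced grid of decay
#' constants spanning the sampled time window (solving the linear
#' subproblem for offset and amplitudes at each candidate), then refined
#' with Levenberg-Marquardt.
#'
#' @param trace A [kinetic_trace()].
#' @param n_phases 1 or 2.
#' @return An [exponential_fit()]; a `"no relaxation"` flag is set when
#'   the fitted amplitudes are negligible (essentially constant signal).
#' @export
fit_exponentials <- function(trace, n_phases = 1L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  n_phases <- as.integer(n_phases)
  if (!n_phases %in% c(1L, 2L)) stop("'n_phases' must be 1 or 2")
  keep <- !trace$excluded
  t <- trace$time[keep]; y <- trace$signal[keep]
  if (length(t) < 10L)
    stop("fewer than 10 usable points after dead-time exclusion")

  k_lo <- 0.1 / max(t); k_hi <- 2 / max(min(t[t > 0]), 1e-6)
  grid <- exp(seq(log(k_lo), log(k_hi), length.out = 25L))

  best <- NULL
  if (n_phases == 1L) {
    for (k in grid) {
      sol <- .exp_linear_solve(t, y, k)
      if (!is.null(sol) && (is.null(best) || sol$sse < best$sse))
        best <- c(sol, list(rates = k))
    }
  } else {
    for (i in seq_along(grid)) for (j in seq_len(i - 1L)) {
      ks <- c(grid[i], grid[j])
      if (ks[1] / ks[2] < 1.5) next
      sol <- .exp_linear_solve(t, y, ks)
      if (!is.null(sol) && (is.null(best) || sol$sse < best$sse))
        best <- c(sol, list(rates = ks))
    }
  }
  if (is.null(best)) stop("exponential fit failed: no valid initialisation")

  # refine all parameters jointly; rates on log scale to stay positive
  par0 <- c(best$offset, best$amplitudes, log(best$rates))
  resid_fun <- function(par) {
    off <- par[1]; A <- par[2:(1 + n_phases)]
    k <- exp(par[(2 + n_phases):(1 + 2 * n_phases)])
    y - (off + drop(vapply(seq_len(n_phases),
                           function(i) A[i] * exp(-k[i] * t),
                           numeric(length(t))) %*% rep(1, n_phases)))
  }
  res <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(res) && sum(res$fvec^2) <= best$sse) {
    par <- res$par
    off <- par[1]; A <- par[2:(1 + n_phases)]
    k <- exp(par[(2 + n_phases):(1 + 2 * n_phases)])
    sse <- sum(res$fvec^2)
  } else {
    off <- best$offset; A <- best$amplitudes; k <- best$rates
    sse <- best$sse
  }

  flags <- character()
  if (sum(abs(A)) < 1e-8 * max(1, abs(off)) ||
      diff(range(y)) < 1e-12 * max(1, abs(off)))
    flags <- c(flags, "no relaxation")
  out <- exponential_fit(n_phases = n_phases, amplitudes = A, rates = k,
                         offset = off, residual_sse = sse, flags = flags)
  attr(out, "n_points") <- length(t)
  out
}

# Small-sample-corrected Akaike criterion for a Gaussian LS fit.
.aicc <- function(sse, n, p) {
  n * log(sse / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
}

#' Choose between one and two kinetic phases for a trace
#'
#' Fits both candidate models and selects two phases only when all three
#' guards hold: (i) the small-sample-corrected Akaike criterion improves
#' by more than `aicc_threshold` for the bi-exponential model, (ii) the
#' minor phase carries at least `min_amp_frac` of the total amplitude,
#' and (iii) the two rates are separated by at least `min_rate_ratio`.
#' This keeps marginal second phases (noise-fitting, near-degenerate
#' rates, vanishing amplitudes) out of the chevron. A fourth guard
#' requires the slower rate to complete at least half an e-folding within
#' the observation window: anything slower is indistinguishable from a
#' drifting offset.
#'
#' @param trace A [kinetic_trace()].
#' @param aicc_threshold Required AICc improvement (default 10).
#' @param min_amp_frac Minimum minor-phase amplitude fraction (default
#'   0.05).
#' @param min_rate_ratio Minimum fast/slow rate ratio (default 3).
#' @return A list of class `phase_selection`: `n_phases` (1 or 2), `fit`
#'   (the selected [exponential_fit()]), `fits` (both candidates, with
#'   AICc stored in `model_score`), and `criteria` (the guard values).
#' @export
select_phase_count <- function(trace, aicc_threshold = 10,
                               min_amp_frac = 0.05, min_rate_ratio = 3) {
  f1 <- fit_exponentials(trace, 1L)
  f2 <- fit_exponentials(trace, 2L)
  n <- sum(!trace$excluded)
  a1 <- .aicc(max(f1$residual_sse, 1e-300), n, 3L)
  a2 <- .aicc(max(f2$residual_sse, 1e-300), n, 5L)
  f1$model_score <- c(aicc_1 = a1, aicc_2 = a2)
  f2$model_score <- c(aicc_1 = a1, aicc_2 = a2)
  amp_frac <- min(abs(f2$amplitudes)) / sum(abs(f2$amplitudes))
  ratio <- f2$rates[1] / f2$rates[2]
  t_span <- diff(range(trace$time[!trace$excluded]))
  resolvable <- f2$rates[2] * t_span >= 0.5
  two <- (a1 - a2) > aicc_threshold &&
    amp_frac >= min_amp_frac && ratio >= min_rate_ratio && resolvable
  structure(
    list(n_phases = if (two) 2L else 1L,
         fit = if (two) f2 else f1,
         fits = list(f1, f2),
         criteria = c(delta_aicc = a1 - a2, minor_amp_frac = amp_frac,
                      rate_ratio = ratio)),
    class = "phase_selection"
  )
}

#' @export
print.phase_selection <- function(x, ...) {
  cat(sprintf("Phase-count selection: %d phase(s) (dAICc = %.1f, minor amp %.1f%%, ratio %.2g)\n",
              x$n_phases, x$criteria["delta_aicc"],
              100 * x$criteria["minor_amp_frac"], x$criteria["rate_ratio"]))
  invisible(x)
}

#' Assemble a chevron dataset from per-concentration exponential fits
#'
#' Two-phase fits contribute their faster rate to the "fast" branch and
#' slower rate to the "slow" branch. Single-phase fits are assigned by
#' rate continuity: the point joins the branch whose nearest point (in
#' denaturant) is closest in ln-rate. Branches may cover disjoint
#' concentration sub-ranges (one phase may be undetectable in part of the
#' range). When fitted branch parameters are supplied via `refine_with`,
#' single-phase points are instead assigned to the branch whose chevron
#' extrapolation is nearer in ln-rate.
#'
#' @param fits A list whose elements are lists with components
#'   `denaturant` (M) and `fit` (an [exponential_fit()] or
#'   [select_phase_count()] result).
#' @param protein Label for the dataset.
#' @param refine_with Optional named list with elements `fast` and/or
#'   `slow`, each a [phase_params()], used to reassign single-phase
#'   points by extrapolated ln-rate distance.
#' @param max_rate Optional resolvability cap (1/s): fitted rates above
#'   it are dropped with a `"rate_cap"` flag. Relaxations faster than
#'   about half the inverse dead time decay mostly before observation
#'   starts, so their fitted rates are unreliable.
#' @param min_rate Optional resolvability floor (1/s): fitted rates below
#'   it are dropped with a `"rate_floor"` flag. Relaxations that do not
#'   complete roughly half an e-folding within the observation window are
#'   indistinguishable from a drifting offset.
#' @param rt Thermal energy RT in kcal/mol.
#' @return A [chevron_dataset()]; duplicate (concentration, phase) pairs
#'   are kept and flagged `"replicate"`.
#' @export
assemble_chevron <- function(fits, protein = "", refine_with = NULL,
                             max_rate = NULL, min_rate = NULL, rt = .RT) {
  if (length(fits) == 0L) stop("empty fit list")
  recs <- lapply(fits, function(f) {
    fit <- f$fit
    if (inherits(fit, "phase_selection")) fit <- fit$fit
    list(x = as.numeric(f$denaturant), fit = fit)
  })
  recs <- recs[order(vapply(recs, `[[`, numeric(1), "x"))]

  den <- numeric(); rate <- numeric(); phase <- character()
  add <- function(x, k, ph) {
    den <<- c(den, x); rate <<- c(rate, k); phase <<- c(phase, ph)
  }
  singles <- list()
  for (r in recs) {
    if (r$fit$n_phases == 2L) {
      add(r$x, r$fit$rates[1], "fast")
      add(r$x, r$fit$rates[2], "slow")
    } else {
      singles[[length(singles) + 1L]] <- list(x = r$x, k = r$fit$rates[1])
    }
  }

  assign_single <- function(x, k) {
    if (!is.null(refine_with) && length(refine_with)) {
      d <- vapply(c("fast", "slow"), function(ph) {
        p <- refine_with[[ph]]
        if (is.null(p)) return(Inf)
        abs(log(k) - log(chevron_rate(x, p, rt)))
      }, numeric(1))
      return(names(d)[which.min(d)])
    }
    branches <- unique(phase)
    if (length(branches) == 0L) return("fast")  # no anchors: single branch
    d <- vapply(branches, function(ph) {
      i <- which(phase == ph)
      j <- i[which.min(abs(den[i] - x))]
      abs(log(k) - log(rate[j]))
    }, numeric(1))
    branches[which.min(d)]
  }
  for (s in singles) add(s$x, s$k, assign_single(s$x, s$k))

  flags <- character()
  if (!is.null(max_rate)) {
    drop <- rate > max_rate
    if (any(drop)) {
      den <- den[!drop]; rate <- rate[!drop]; phase <- phase[!drop]
      flags <- c(flags, "rate_cap")
    }
  }
  if (!is.null(min_rate)) {
    drop <- rate < min_rate
    if (any(drop)) {
      den <- den[!drop]; rate <- rate[!drop]; phase <- phase[!drop]
      flags <- c(flags, "rate_floor")
    }
  }
  if (anyDuplicated(paste(den, phase))) flags <- c(flags, "replicate")
  ord <- order(den, phase, rate)
  chevron_dataset(den[ord], rate[ord], phase[ord], protein = protein,
                  flags = flags)
}
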