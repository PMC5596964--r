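#' Equilibrium titration curve
#'
#' Container for one equilibrium chemical-denaturation experiment: a scalar
#' fluorescence (or other spectroscopic) signal recorded at a series of
#' denaturant concentrations.
#'
#' @param denaturant Numeric vector of denaturant concentrations (M),
#'   strictly increasing, all non-negative.
#' @param signal Numeric vector of signal values, same length as
#'   `denaturant`. At least 8 points are required: the two-state model with
#'   sloping baselines has 6 free parameters.
#' @param label Optional free-text label (e.g. the protein name).
#' @return An object of class `titration_curve`.
#' @export
titration_curve <- function(denaturant, signal, label = "") {
  denaturant <- as.numeric(denaturant)
  signal <- as.numeric(signal)
  if (length(denaturant) != length(signal))
    stop("'denaturant' and 'signal' must have the same length")
  if (length(denaturant) < 8L)
    stop("at least 8 titration points are required (6 model parameters)")
  if (any(!is.finite(denaturant)) || any(!is.finite(signal)))
    stop("non-finite values in titration data")
  if (any(denaturant < 0))
    stop("denaturant concentrations must be >= 0")
  if (any(diff(denaturant) <= 0))
    stop("denaturant concentrations must be strictly increasing")
  structure(
    list(denaturant = denaturant, signal = signal, label = as.character(label)),
    class = "titration_curve"
  )
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("Titration curve%s: %d points, %.2f-%.2f M\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$denaturant), min(x$denaturant), max(x$denaturant)))
  invisible(x)
}

#' Two-state equilibrium fit result
#'
#' Holds the parameters of the two-state denaturation model with linear
#' baselines: native intercept/slope (`a_N`, `b_N`), denatured
#' intercept/slope (`a_D`, `b_D`), the equilibrium m-value `m`
#' (kcal/mol/M) and the midpoint `D50` (M). The unfolding free energy in
#' water, `dG = m * D50` (kcal/mol), is derived and stored.
#'
#' @param a_N,b_N Native-baseline intercept and slope (signal units,
#'   signal units per M).
#' @param a_D,b_D Denatured-baseline intercept and slope.
#' @param m Equilibrium m-value, kcal/mol/M; must be > 0.
#' @param D50 Transition midpoint, M; must be > 0.
#' @param se Optional named numeric vector of standard errors.
#' @return An object of class `two_state_fit`.
#' @export
two_state_fit <- function(a_N, b_N, a_D, b_D, m, D50, se = NULL) {
  stopifnot(is.numeric(m), is.numeric(D50))
  if (!is.finite(m) || m <= 0) stop("'m' must be positive")
  if (!is.finite(D50) || D50 <= 0) stop("'D50' must be positive")
  out <- structure(
    list(a_N = as.numeric(a_N), b_N = as.numeric(b_N),
         a_D = as.numeric(a_D), b_D = as.numeric(b_D),
         m = as.numeric(m), D50 = as.numeric(D50),
         dG = as.numeric(m) * as.numeric(D50),
         se = se),
    class = "two_state_fit"
  )
  out
}

#' @export
print.two_state_fit <- function(x, ...) {
  fmt <- function(p) {
    v <- sprintf("%.4g", x[[p]])
    if (!is.null(x$se) && p %in% names(x$se))
      v <- paste0(v, " (se ", sprintf("%.2g", x$se[[p]]), ")")
    v
  }
  cat("Two-state equilibrium fit\n")
  cat("  m   =", fmt("m"), "kcal/mol/M\n")
  cat("  D50 =", fmt("D50"), "M\n")
  cat("  dG  =", sprintf("%.4g", x$dG), "kcal/mol (= m * D50)\n")
  cat(sprintf("  baselines: native %.4g + %.4g x, denatured %.4g + %.4g x\n",
              x$a_N, x$b_N, x$a_D, x$b_D))
  invisible(x)
}

#' Stopped-flow kinetic trace
#'
#' One mixing experiment: fluorescence signal versus time at a fixed final
#' denaturant concentration. Points recorded before the instrument dead
#' time are kept but flagged `excluded` and ignored by the fitters.
#'
#' @param time Numeric vector of times (s), strictly increasing, all >= 0.
#' @param signal Numeric vector of signal values, same length.
#' @param denaturant_final Final denaturant concentration after mixing (M).
#' @param direction `"folding"` or `"unfolding"`.
#' @param dead_time Instrument dead time in seconds (default 0.0034, the
#'   3.4 ms typical of a stopped-flow mixer).
#' @return An object of class `kinetic_trace` with a logical `excluded`
#'   component marking points at `time < dead_time`.
#' @export
kinetic_trace <- function(time, signal, denaturant_final,
                          direction = c("folding", "unfolding"),
                          dead_time = 0.0034) {
  direction <- match.arg(direction)
  time <- as.numeric(time); signal <- as.numeric(signal)
  if (length(time) != length(signal))
    stop("'time' and 'signal' must have the same length")
  if (length(time) == 0L) stop("empty kinetic trace")
  if (any(!is.finite(time)) || any(!is.finite(signal)))
    stop("non-finite values in kinetic trace")
  if (any(time < 0)) stop("times must be >= 0")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  stopifnot(is.numeric(denaturant_final), denaturant_final >= 0,
            is.numeric(dead_time), dead_time >= 0)
  structure(
    list(time = time, signal = signal,
         denaturant_final = as.numeric(denaturant_final),
         direction = direction, dead_time = as.numeric(dead_time),
         excluded = time < dead_time),
    class = "kinetic_trace"
  )
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf(
    "Kinetic trace (%s, %.2f M): %d points (%d inside dead time), %.3g-%.3g s\n",
    x$direction, x$denaturant_final, length(x$time), sum(x$excluded),
    min(x$time), max(x$time)))
  invisible(x)
}

#' Exponential relaxation fit result
#'
#' @param n_phases Number of exponential phases (1 or 2).
#' @param amplitudes Per-phase amplitudes, extrapolated to t = 0.
#' @param rates Per-phase decay rates (1/s), sorted descending; all > 0.
#' @param offset Signal offset (the t -> Inf plateau).
#' @param residual_sse Residual sum of squares of the fit.
#' @param model_score Named numeric of information-criterion values for the
#'   candidate phase counts (small-sample corrected AIC), when available.
#' @param se Optional named standard errors.
#' @param flags Character vector of quality flags (e.g. "no relaxation").
#' @return An object of class `exponential_fit`.
#' @export
exponential_fit <- function(n_phases, amplitudes, rates, offset,
                            residual_sse, model_score = NULL, se = NULL,
                            flags = character()) {
  n_phases <- as.integer(n_phases)
  if (!n_phases %in% c(1L, 2L)) stop("'n_phases' must be 1 or 2")
  rates <- as.numeric(rates); amplitudes <- as.numeric(amplitudes)
  if (length(rates) != n_phases || length(amplitudes) != n_phases)
    stop("'rates' and 'amplitudes' must have length n_phases")
  if (any(rates <= 0)) stop("rates must be positive")
  ord <- order(rates, decreasing = TRUE)
  structure(
    list(n_phases = n_phases, amplitudes = amplitudes[ord],
         rates = rates[ord], offset = as.numeric(offset),
         residual_sse = as.numeric(residual_sse),
         model_score = model_score, se = se, flags = flags),
    class = "exponential_fit"
  )
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Exponential fit: %d phase(s)\n", x$n_phases))
  for (i in seq_len(x$n_phases))
    cat(sprintf("  phase %d: k = %.4g /s, amplitude = %.4g\n",
                i, x$rates[i], x$amplitudes[i]))
  cat(sprintf("  offset = %.4g, SSE = %.3g\n", x$offset, x$residual_sse))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Chevron phase parameters
#'
#' Parameter set of the two-limb chevron equation for one kinetic phase:
#' folding and unfolding rate constants extrapolated to water (`kf0`,
#' `ku0`, 1/s) and the kinetic m-values (`mf`, `mu`, kcal/mol/M, stored as
#' magnitudes).
#'
#' @param kf0 Folding rate in water (1/s), > 0.
#' @param mf Folding kinetic m-value magnitude, >= 0.
#' @param ku0 Unfolding rate in water (1/s), > 0.
#' @param mu Unfolding kinetic m-value magnitude, >= 0.
#' @param se Optional named standard errors.
#' @param phase_label `"fast"` or `"slow"`.
#' @param fit_range Optional denaturant range c(min, max) over which the
#'   phase was observed.
#' @param flags Character vector of quality flags.
#' @return An object of class `phase_params`.
#' @export
phase_params <- function(kf0, mf, ku0, mu, se = NULL,
                         phase_label = c("fast", "slow"),
                         fit_range = NULL, flags = character()) {
  phase_label <- match.arg(phase_label)
  stopifnot(is.numeric(kf0), is.numeric(ku0), is.numeric(mf), is.numeric(mu))
  if (kf0 <= 0) stop("'kf0' must be positive")
  if (ku0 <= 0) stop("'ku0' must be positive")
  if (mf < 0) stop("'mf' must be >= 0 (stored as magnitude)")
  if (mu < 0) stop("'mu' must be >= 0 (stored as magnitude)")
  structure(
    list(kf0 = as.numeric(kf0), mf = as.numeric(mf),
         ku0 = as.numeric(ku0), mu = as.numeric(mu),
         se = se, phase_label = phase_label,
         fit_range = fit_range, flags = flags),
    class = "phase_params"
  )
}

#' @export
print.phase_params <- function(x, ...) {
  cat(sprintf("Chevron phase parameters [%s]\n", x$phase_label))
  cat(sprintf("  kf0 = %.4g /s, mf = %.4g kcal/mol/M\n", x$kf0, x$mf))
  cat(sprintf("  ku0 = %.4g /s, mu = %.4g kcal/mol/M\n", x$ku0, x$mu))
  if (!is.null(x$fit_range))
    cat(sprintf("  fitted over %.2f-%.2f M\n", x$fit_range[1], x$fit_range[2]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Chevron dataset
#'
#' Observed relaxation rates versus denaturant concentration, each point
#' labelled with the kinetic phase ("fast" or "slow") it belongs to.
#'
#' @param denaturant Numeric vector of concentrations (M), >= 0.
#' @param rate Numeric vector of observed relaxation rates (1/s), > 0.
#' @param phase Character vector of phase labels, each "fast" or "slow".
#' @param protein Optional free-text protein name.
#' @param flags Character vector of dataset-level flags.
#' @return An object of class `chevron_dataset` containing a data.frame
#'   `points` with columns denaturant, rate, phase.
#' @export
chevron_dataset <- function(denaturant, rate, phase, protein = "",
                            flags = character()) {
  denaturant <- as.numeric(denaturant); rate <- as.numeric(rate)
  phase <- as.character(phase)
  n <- length(denaturant)
  if (length(rate) != n || length(phase) != n)
    stop("'denaturant', 'rate' and 'phase' must have the same length")
  if (any(!is.finite(denaturant)) || any(!is.finite(rate)))
    stop("non-finite values in chevron data")
  if (any(denaturant < 0)) stop("denaturant concentrations must be >= 0")
  if (any(rate <= 0)) stop("observed rates must be positive")
  bad <- setdiff(unique(phase), c("fast", "slow"))
  if (length(bad))
    stop("invalid phase label(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed labels are 'fast' and 'slow'")
  structure(
    list(points = data.frame(denaturant = denaturant, rate = rate,
                             phase = phase, stringsAsFactors = FALSE),
         protein = as.character(protein), flags = flags),
    class = "chevron_dataset"
  )
}

#' @export
print.chevron_dataset <- function(x, ...) {
  tab <- table(x$points$phase)
  cat(sprintf("Chevron dataset%s: %d points (%s)\n",
              if (nzchar(x$protein)) paste0(" [", x$protein, "]") else "",
              nrow(x$points),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
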