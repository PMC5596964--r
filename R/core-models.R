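#' Mean residue ellipticity from observed ellipticity
#'
#' Normalises a raw circular-dichroism ellipticity to a per-residue value:
#' `100 * theta_obs / (d * C * (n - 1))`, where the `n - 1` counts peptide
#' bonds rather than residues.
#'
#' @param theta_obs Observed ellipticity (deg).
#' @param d Cuvette path length (cm), > 0.
#' @param C Molar protein concentration (M), > 0.
#' @param n Number of amino-acid residues, >= 2.
#' @return Mean residue ellipticity (deg cm^2/dmol, up to the unit
#'   convention of `C`).
#' @examples
#' mre_from_ellipticity(0.01, d = 0.2, C = 25e-6, n = 74)
#' @export
mre_from_ellipticity <- function(theta_obs, d, C, n) {
  if (!is.numeric(d) || d <= 0) stop("'d' (path length) must be positive")
  if (!is.numeric(C) || C <= 0) stop("'C' (concentration) must be positive")
  if (!is.numeric(n) || n < 2) stop("'n' (residue count) must be >= 2")
  100 * theta_obs / (d * C * (n - 1))
}

#' Equilibrium fraction unfolded under the two-state model
#'
#' The linear extrapolation method gives `dG(x) = m * (D50 - x)`, so the
#' unfolded population is a logistic function of denaturant concentration:
#' `exp(m (x - D50) / RT) / (1 + exp(m (x - D50) / RT))`.
#'
#' @param x Denaturant concentration (M); vectorised.
#' @param m Equilibrium m-value (kcal/mol/M), > 0.
#' @param D50 Transition midpoint (M).
#' @param rt Thermal energy RT in kcal/mol (default 298 K value).
#' @return Fraction unfolded in (0, 1); exactly 0.5 at `x = D50`.
#' @examples
#' fraction_unfolded(2.20, m = 1.54, D50 = 2.20)  # 0.5
#' @export
fraction_unfolded <- function(x, m, D50, rt = .RT) {
  if (!is.numeric(m) || m <= 0) stop("'m' must be positive")
  stats::plogis(m * (x - D50) / rt)
}

#' Predicted signal of a two-state titration with sloping baselines
#'
#' Evaluates the standard two-state denaturation curve
#' `(a_N + b_N x + (a_D + b_D x) E) / (1 + E)` with
#' `E = exp(m (x - D50) / RT)`: a population-weighted average of the
#' linear native and denatured baselines.
#'
#' @param x Denaturant concentration (M); vectorised.
#' @param fit A [two_state_fit()] object (or any list with components
#'   a_N, b_N, a_D, b_D, m, D50).
#' @param rt Thermal energy RT in kcal/mol.
#' @return Predicted signal at each `x`.
#' @export
eval_two_state_titration <- function(x, fit, rt = .RT) {
  E <- exp(fit$m * (x - fit$D50) / rt)
  (fit$a_N + fit$b_N * x + (fit$a_D + fit$b_D * x) * E) / (1 + E)
}

#' Observed relaxation rate of the two-limb chevron equation
#'
#' Under linear free-energy relations both microscopic rate constants
#' depend exponentially on denaturant, and the observed relaxation rate of
#' a (pseudo) two-state step is their sum:
#' `k_obs(x) = kf0 exp(-mf x / RT) + ku0 exp(+mu x / RT)`.
#' Its logarithm is convex in `x` (the chevron "V").
#'
#' @param x Denaturant concentration (M); vectorised.
#' @param p A [phase_params()] object (or list with kf0, mf, ku0, mu).
#' @param rt Thermal energy RT in kcal/mol.
#' @return Observed relaxation rate (1/s).
#' @examples
#' p <- phase_params(kf0 = 15.9, mf = 0.3, ku0 = 2.7, mu = 0.4)
#' chevron_rate(0, p)  # kf0 + ku0
#' @export
chevron_rate <- function(x, p, rt = .RT) {
  p$kf0 * exp(-p$mf * x / rt) + p$ku0 * exp(p$mu * x / rt)
}

#' Free-energy change from a pair of rate constants
#'
#' For one folding step, `dG = -RT ln(kf / ku)` in the folding direction:
#' negative when folding is faster than unfolding.
#'
#' @param kf Folding rate constant (1/s), > 0.
#' @param ku Unfolding rate constant (1/s), > 0.
#' @param rt Thermal energy RT in kcal/mol.
#' @return Free-energy change (kcal/mol).
#' @examples
#' delta_g_from_rates(15.9, 2.7)  # about -1.05
#' @export
delta_g_from_rates <- function(kf, ku, rt = .RT) {
  if (any(!is.numeric(kf)) || any(kf <= 0)) stop("'kf' must be positive")
  if (any(!is.numeric(ku)) || any(ku <= 0)) stop("'ku' must be positive")
  -rt * log(kf / ku)
}

#' Transition midpoint from stability and m-value
#'
#' Under the linear extrapolation method `dG = m * D50`, so the midpoint is
#' simply `dG / m`.
#'
#' @param dG Unfolding free energy in water (kcal/mol).
#' @param m Equilibrium m-value (kcal/mol/M), > 0.
#' @return Midpoint denaturant concentration (M).
#' @examples
#' d50_from_dg_m(3.39, 1.54)  # 2.20 M
#' @export
d50_from_dg_m <- function(dG, m) {
  if (!is.numeric(m) || any(m <= 0)) stop("'m' must be positive")
  dG / m
}

#' Equilibrium m-value implied by kinetic m-values
#'
#' The equilibrium m-value of a step equals the sum of the magnitudes of
#' its folding and unfolding kinetic m-values (the transition state lies
#' between the end states on the solvent-exposure axis).
#'
#' @param mf Folding kinetic m-value magnitude (kcal/mol/M), >= 0.
#' @param mu Unfolding kinetic m-value magnitude (kcal/mol/M), >= 0.
#' @return Equilibrium m-value (kcal/mol/M).
#' @examples
#' m_eq_from_kinetic(0.3, 0.4)  # 0.7
#' @export
m_eq_from_kinetic <- function(mf, mu) {
  if (any(mf < 0) || any(mu < 0)) stop("kinetic m-values must be >= 0")
  abs(mf) + abs(mu)
}

#' Analytic minimum of a chevron
#'
#' The chevron `kf0 exp(-mf x/RT) + ku0 exp(+mu x/RT)` has an interior
#' minimum at `x* = RT / (mf + mu) * ln(kf0 mf / (ku0 mu))` provided both
#' m-values are strictly positive.
#'
#' @param p A [phase_params()] object.
#' @param rt Thermal energy RT in kcal/mol.
#' @return A list with `denaturant` (M), `rate` (1/s) and logical
#'   `boundary` (TRUE when an m-value is zero so no interior minimum
#'   exists; `denaturant` is then NA and `rate` is the x = 0 rate).
#' @export
chevron_minimum <- function(p, rt = .RT) {
  if (p$mf + p$mu <= 0) stop("'mf' + 'mu' must be positive")
  if (p$mf == 0 || p$mu == 0) {
    return(list(denaturant = NA_real_, rate = chevron_rate(0, p, rt),
                boundary = TRUE))
  }
  xstar <- rt / (p$mf + p$mu) * log(p$kf0 * p$mf / (p$ku0 * p$mu))
  list(denaturant = xstar, rate = chevron_rate(xstar, p, rt),
       boundary = FALSE)
}
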