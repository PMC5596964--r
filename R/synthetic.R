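#' Three-state folding scheme
#'
#' Ground truth for the synthetic-data generator: a linear three-state
#' mechanism over the unfolded (U), intermediate (I) and native (N)
#' ensembles. In the on-pathway topology the chain is U = I = N; in the
#' off-pathway topology the intermediate branches from the unfolded state
#' (I = U = N), so step 2 connects U and N directly.
#'
#' Every microscopic rate constant obeys a linear free-energy relation in
#' denaturant: folding-direction rates decrease as `k0 exp(-m x / RT)` and
#' unfolding-direction rates increase as `k0 exp(+m x / RT)`.
#'
#' @param k1_0,m1 Step-1 forward (folding-direction) rate in water (1/s)
#'   and its m-value (kcal/mol/M). On-pathway: U -> I.
#' @param k1r_0,m1r Step-1 reverse rate and m-value. On-pathway: I -> U.
#' @param k2_0,m2 Step-2 forward rate and m-value. On-pathway: I -> N;
#'   off-pathway: U -> N.
#' @param k2r_0,m2r Step-2 reverse rate and m-value.
#' @param fluor Numeric length-3 vector of per-species fluorescence
#'   coefficients, in state order (U, I, N).
#' @param topology `"on_pathway"` or `"off_pathway"`.
#' @return An object of class `three_state_scheme`.
#' @examples
#' sc <- three_state_scheme(k1_0 = 15.9, m1 = 0.3, k1r_0 = 2.7, m1r = 0.4,
#'                          k2_0 = 2.4, m2 = 0.4, k2r_0 = 0.1, m2r = 0.5)
#' scheme_free_energies(sc)
#' @export
three_state_scheme <- function(k1_0, m1, k1r_0, m1r, k2_0, m2, k2r_0, m2r,
                               fluor = c(U = 1, I = 0.5, N = 0),
                               topology = c("on_pathway", "off_pathway")) {
  topology <- match.arg(topology)
  ks <- c(k1_0 = k1_0, k1r_0 = k1r_0, k2_0 = k2_0, k2r_0 = k2r_0)
  ms <- c(m1 = m1, m1r = m1r, m2 = m2, m2r = m2r)
  if (any(!is.finite(ks)) || any(ks <= 0))
    stop("all rate constants must be positive and finite")
  if (any(!is.finite(ms)) || any(ms < 0))
    stop("all m-values must be >= 0")
  if (length(fluor) != 3L || any(!is.finite(fluor)))
    stop("'fluor' must be 3 finite coefficients (U, I, N)")
  structure(
    list(k1_0 = k1_0, m1 = m1, k1r_0 = k1r_0, m1r = m1r,
         k2_0 = k2_0, m2 = m2, k2r_0 = k2r_0, m2r = m2r,
         fluor = as.numeric(fluor), topology = topology),
    class = "three_state_scheme"
  )
}

#' @export
print.three_state_scheme <- function(x, ...) {
  arrows <- if (x$topology == "on_pathway") c("U=I", "I=N") else c("U=I", "U=N")
  cat(sprintf("Three-state scheme (%s)\n", x$topology))
  cat(sprintf("  step 1 %s: k = %.4g / %.4g /s, m = %.3g / %.3g\n",
              arrows[1], x$k1_0, x$k1r_0, x$m1, x$m1r))
  cat(sprintf("  step 2 %s: k = %.4g / %.4g /s, m = %.3g / %.3g\n",
              arrows[2], x$k2_0, x$k2r_0, x$m2, x$m2r))
  invisible(x)
}

#' Per-step and total free energies of a scheme
#'
#' @param scheme A [three_state_scheme()].
#' @param rt Thermal energy RT in kcal/mol.
#' @return List with `step1`, `step2` and `total` free energies (kcal/mol,
#'   folding direction; total = step1 + step2) and `m_total`, the sum of
#'   all four m-value magnitudes (the equilibrium m of the U -> N
#'   transition for an on-pathway chain).
#' @export
scheme_free_energies <- function(scheme, rt = .RT) {
  dg1 <- delta_g_from_rates(scheme$k1_0, scheme$k1r_0, rt)
  dg2 <- delta_g_from_rates(scheme$k2_0, scheme$k2r_0, rt)
  list(step1 = dg1, step2 = dg2, total = dg1 + dg2,
       m_total = scheme$m1 + scheme$m1r + scheme$m2 + scheme$m2r)
}

#' Noise specification for the simulators
#'
#' @param trace_sd Additive Gaussian sd on kinetic-trace signals.
#' @param titration_sd Additive Gaussian sd on titration signals.
#' @param rate_rel_sd Relative sd of multiplicative lognormal noise on
#'   chevron rates (rates span decades, so noise is multiplicative).
#' @param seed Integer RNG seed; every simulator call is deterministic
#'   given its `noise$seed`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(trace_sd = 0.01, titration_sd = 2,
                       rate_rel_sd = 0.05, seed = 0L) {
  if (any(c(trace_sd, titration_sd, rate_rel_sd) < 0))
    stop("noise standard deviations must be >= 0")
  structure(list(trace_sd = trace_sd, titration_sd = titration_sd,
                 rate_rel_sd = rate_rel_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

# Microscopic rates of the scheme at denaturant x (vector of 4:
# step1 forward/reverse, step2 forward/reverse).
scheme_rates_at <- function(scheme, x, rt = .RT) {
  c(k1  = scheme$k1_0  * exp(-scheme$m1  * x / rt),
    k1r = scheme$k1r_0 * exp(+scheme$m1r * x / rt),
    k2  = scheme$k2_0  * exp(-scheme$m2  * x / rt),
    k2r = scheme$k2r_0 * exp(+scheme$m2r * x / rt))
}

#' Rate matrix (generator) of the three-state kinetics
#'
#' Builds the 3x3 generator Q of the master equation dp/dt = Q p over the
#' state order (U, I, N) at denaturant concentration `x`. Off-diagonal
#' entry Q\[i, j\] is the microscopic rate from state j to state i;
#' columns sum to zero (probability conservation).
#'
#' @param scheme A [three_state_scheme()].
#' @param x Denaturant concentration (M), >= 0.
#' @param rt Thermal energy RT in kcal/mol.
#' @return A 3x3 numeric matrix with dimnames (U, I, N).
#' @export
rate_matrix <- function(scheme, x, rt = .RT) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0)
  k <- scheme_rates_at(scheme, x, rt)
  Q <- matrix(0, 3, 3, dimnames = list(c("U", "I", "N"), c("U", "I", "N")))
  if (scheme$topology == "on_pathway") {
    Q["I", "U"] <- k[["k1"]]   # U -> I
    Q["U", "I"] <- k[["k1r"]]  # I -> U
    Q["N", "I"] <- k[["k2"]]   # I -> N
    Q["I", "N"] <- k[["k2r"]]  # N -> I
  } else {
    Q["I", "U"] <- k[["k1"]]   # U -> I (dead-end branch)
    Q["U", "I"] <- k[["k1r"]]  # I -> U
    Q["N", "U"] <- k[["k2"]]   # U -> N
    Q["U", "N"] <- k[["k2r"]]  # N -> U
  }
  diag(Q) <- -colSums(Q)
  Q
}

#' Relaxation rates (nonzero eigenvalue magnitudes) of a scheme
#'
#' The observable decay constants of the linear three-state kinetics are
#' the magnitudes of the two nonzero eigenvalues of the rate matrix.
#'
#' @param scheme A [three_state_scheme()].
#' @param x Denaturant concentration (M).
#' @param rt Thermal energy RT in kcal/mol.
#' @return Named numeric c(fast = ..., slow = ...), both > 0, sorted
#'   descending. A `degenerate` attribute is set to TRUE (with a warning)
#'   when the two rates agree within 1e-9 relative.
#' @export
relaxation_rates <- function(scheme, x, rt = .RT) {
  Q <- rate_matrix(scheme, x, rt)
  ev <- eigen(Q, only.values = TRUE)$values
  # a reversible chain has real spectrum; tolerate numerical imaginary dust
  ev <- Re(ev)[order(abs(Re(ev)))]
  lam <- abs(ev[2:3])
  lam <- sort(lam, decreasing = TRUE)
  names(lam) <- c("fast", "slow")
  degenerate <- (lam[1] - lam[2]) <= 1e-9 * lam[1]
  if (degenerate) warning("relaxation rates are numerically degenerate")
  attr(lam, "degenerate") <- unname(degenerate)
  lam
}

# Analytic propagator: populations p(t) for the master equation from p0,
# via eigen-decomposition of Q. Returns length(t) x 3 matrix.
propagate_populations <- function(Q, p0, t) {
  es <- eigen(Q)
  V <- es$vectors
  coef <- solve(V, p0)
  # p(t) = sum_j coef_j * exp(lambda_j t) * v_j; reversible chains have a
  # real spectrum, so only numerical imaginary dust is discarded
  out <- matrix(0, length(t), 3)
  for (j in 1:3)
    out <- out + Re(outer(exp(es$values[j] * t), V[, j] * coef[j]))
  colnames(out) <- c("U", "I", "N")
  out
}

#' Simulate a stopped-flow kinetic trace
#'
#' Solves the three-state master equation analytically from the mixing
#' initial condition (all-U for folding, all-N for unfolding, or the
#' equilibrium populations at a pre-mix denaturant concentration when
#' `premix` is given), projects populations onto the per-species
#' fluorescence coefficients, and adds Gaussian noise.
#'
#' @param scheme A [three_state_scheme()].
#' @param x Final denaturant concentration after mixing (M).
#' @param direction `"folding"` or `"unfolding"`.
#' @param t_grid Increasing time grid (s), >= 20 points. Default:
#'   200 log-spaced points from 1 ms to 50 s.
#' @param noise A [noise_spec()].
#' @param premix Optional pre-mix denaturant concentration; when supplied
#'   the initial populations are the equilibrium distribution at that
#'   concentration instead of a pure species.
#' @param rt Thermal energy RT in kcal/mol.
#' @return A [kinetic_trace()] at `x` with the default 3.4 ms dead time.
#' @export
simulate_trace <- function(scheme, x, direction = c("folding", "unfolding"),
                           t_grid = default_time_grid(),
                           noise = noise_spec(), premix = NULL, rt = .RT) {
  direction <- match.arg(direction)
  if (length(t_grid) == 0L) stop("empty time grid")
  if (length(t_grid) < 20L) stop("at least 20 time points are required")
  if (any(diff(t_grid) <= 0)) stop("'t_grid' must be strictly increasing")
  Q <- rate_matrix(scheme, x, rt)
  p0 <- if (!is.null(premix)) {
    equilibrium_populations(scheme, premix, rt)
  } else if (direction == "folding") c(1, 0, 0) else c(0, 0, 1)
  pops <- propagate_populations(Q, p0, t_grid)
  sig <- drop(pops %*% scheme$fluor)
  if (noise$trace_sd > 0)
    sig <- sig + with_seed(noise$seed,
                           stats::rnorm(length(sig), sd = noise$trace_sd))
  kinetic_trace(t_grid, sig, denaturant_final = x, direction = direction)
}

#' Equilibrium populations of a scheme at a denaturant concentration
#'
#' @param scheme A [three_state_scheme()].
#' @param x Denaturant concentration (M).
#' @param rt Thermal energy RT in kcal/mol.
#' @return Numeric length-3 probability vector (U, I, N).
#' @export
equilibrium_populations <- function(scheme, x, rt = .RT) {
  k <- scheme_rates_at(scheme, x, rt)
  if (scheme$topology == "on_pathway") {
    # relative weights: U = 1, I = K1, N = K1 K2
    w <- c(1, k[["k1"]] / k[["k1r"]],
           k[["k1"]] / k[["k1r"]] * k[["k2"]] / k[["k2r"]])
  } else {
    w <- c(1, k[["k1"]] / k[["k1r"]], k[["k2"]] / k[["k2r"]])
  }
  stats::setNames(w / sum(w), c("U", "I", "N"))
}

#' Simulate an equilibrium titration curve
#'
#' Noise-free values follow the two-state model with sloping baselines at
#' the supplied stability and m-value; Gaussian noise of sd
#' `noise$titration_sd` is added.
#'
#' @param dG Unfolding free energy in water (kcal/mol).
#' @param m Equilibrium m-value (kcal/mol/M), > 0.
#' @param baselines Numeric length-4 `c(a_N, b_N, a_D, b_D)`.
#' @param grid Denaturant grid (M). Default 0 to 8 M in 0.2 M steps, the
#'   usual fluorimeter titration layout.
#' @param noise A [noise_spec()].
#' @param label Label passed to the curve.
#' @param rt Thermal energy RT in kcal/mol.
#' @return A [titration_curve()].
#' @export
simulate_titration <- function(dG, m, baselines = c(100, -2, 200, 1),
                               grid = seq(0, 8, by = 0.2),
                               noise = noise_spec(), label = "", rt = .RT) {
  if (!is.numeric(m) || m <= 0) stop("'m' must be positive")
  if (length(grid) == 0L) stop("empty denaturant grid")
  fit <- two_state_fit(a_N = baselines[1], b_N = baselines[2],
                       a_D = baselines[3], b_D = baselines[4],
                       m = m, D50 = dG / m)
  y <- eval_two_state_titration(grid, fit, rt)
  if (noise$titration_sd > 0)
    y <- y + with_seed(noise$seed,
                       stats::rnorm(length(y), sd = noise$titration_sd))
  titration_curve(grid, y, label = label)
}

#' Simulate a chevron dataset
#'
#' For a [phase_params()] input the noise-free rates follow the two-limb
#' chevron equation exactly (one branch, labelled by the phase). For a
#' [three_state_scheme()] input the rates are the two relaxation
#' eigenvalue magnitudes at each concentration (two branches).
#' Multiplicative lognormal noise with relative sd `noise$rate_rel_sd` is
#' applied.
#'
#' @param params A [phase_params()] or [three_state_scheme()].
#' @param grid Denaturant grid (M), nonempty.
#' @param noise A [noise_spec()].
#' @param protein Label for the dataset.
#' @param rt Thermal energy RT in kcal/mol.
#' @return A [chevron_dataset()].
#' @export
simulate_chevron <- function(params, grid, noise = noise_spec(),
                             protein = "", rt = .RT) {
  if (length(grid) == 0L) stop("empty denaturant grid")
  if (inherits(params, "phase_params")) {
    den <- grid
    rates <- chevron_rate(grid, params, rt)
    phase <- rep(params$phase_label, length(grid))
  } else if (inherits(params, "three_state_scheme")) {
    lam <- vapply(grid, function(x)
      suppressWarnings(relaxation_rates(params, x, rt)), numeric(2))
    den <- rep(grid, each = 2)
    rates <- as.numeric(lam)
    phase <- rep(c("fast", "slow"), times = length(grid))
  } else {
    stop("'params' must be a phase_params or three_state_scheme object")
  }
  if (noise$rate_rel_sd > 0) {
    # lognormal with sdlog = rel sd (first order); multiplicative noise
    fac <- with_seed(noise$seed,
                     exp(stats::rnorm(length(rates), sd = noise$rate_rel_sd)))
    rates <- rates * fac
  }
  chevron_dataset(den, rates, phase, protein = protein)
}
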