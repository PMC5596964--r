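#' Per-phase thermodynamics from chevron parameters
#'
#' Converts one phase's chevron parameters into step thermodynamics:
#' `dG = -RT ln(kf0 / ku0)` (folding direction, negative for a stabilising
#' step) and the equilibrium m-value `m_eq = mf + mu`. The standard error
#' of `dG` is propagated to first order from the rate standard errors:
#' `se(dG) = RT sqrt((se_kf/kf0)^2 + (se_ku/ku0)^2)`.
#'
#' @param p A [phase_params()].
#' @param rt Thermal energy RT in kcal/mol.
#' @return A list with `phase_label`, `dG`, `m_eq` and `se` (se of dG; NA
#'   when the rate SEs are unavailable).
#' @examples
#' phase_thermodynamics(phase_params(15.9, 0.3, 2.7, 0.4))
#' @export
phase_thermodynamics <- function(p, rt = .RT) {
  stopifnot(inherits(p, "phase_params"))
  dG <- delta_g_from_rates(p$kf0, p$ku0, rt)
  m_eq <- m_eq_from_kinetic(p$mf, p$mu)
  se <- NA_real_
  if (!is.null(p$se) && all(c("kf0", "ku0") %in% names(p$se)))
    se <- rt * sqrt((p$se[["kf0"]] / p$kf0)^2 + (p$se[["ku0"]] / p$ku0)^2)
  list(phase_label = p$phase_label, dG = dG, m_eq = m_eq, se = se)
}

#' Classify a folding intermediate as on- or off-pathway
#'
#' Compares free energies from kinetics with the equilibrium stability.
#' For an on-pathway intermediate the steps are sequential, so the summed
#' magnitudes of the per-step free energies should match the equilibrium
#' unfolding free energy; for an off-pathway intermediate the U-N
#' transition is a single one of the observed steps, so one phase alone
#' should match it while the sum overshoots. Formally, with
#' `d_sum = | sum_i |dG_i| - dG_eq |` and `d_i = | |dG_i| - dG_eq |`:
#' * `on_pathway` when `d_sum <= tol` and no single phase passes the same
#'   test with a strictly smaller discrepancy;
#' * `off_pathway` when some `d_i <= tol` while `d_sum > tol`;
#' * `ambiguous` otherwise, and always when only one phase has a finite
#'   free energy (single-phase evidence cannot separate the hypotheses).
#'
#' The default tolerance is `max(2 * combined propagated SE, 0.5)`
#' kcal/mol; the floor reflects typical fit-to-fit scatter of chevron
#' free energies.
#'
#' @param phases List of [phase_params()] objects, or of lists with
#'   components `dG` (and optionally `phase_label`, `m_eq`, `se`) for
#'   pre-computed step free energies.
#' @param eq A [two_state_fit()] (or list with `dG`, optionally `m` and
#'   `se["dG"]`) from the equilibrium titration.
#' @param tol Optional tolerance (kcal/mol) overriding the default.
#' @param rt Thermal energy RT in kcal/mol.
#' @return An object of class `pathway_report`.
#' @export
classify_pathway <- function(phases, eq, tol = NULL, rt = .RT) {
  if (length(phases) == 0L) stop("'phases' must contain at least one phase")
  per <- lapply(seq_along(phases), function(i) {
    ph <- phases[[i]]
    if (inherits(ph, "phase_params")) return(phase_thermodynamics(ph, rt))
    if (is.list(ph) && !is.null(ph$dG)) {
      return(list(
        phase_label = if (!is.null(ph$phase_label)) ph$phase_label
                      else paste0("phase", i),
        dG = ph$dG,
        m_eq = if (!is.null(ph$m_eq)) ph$m_eq else NA_real_,
        se = if (!is.null(ph$se)) ph$se else NA_real_))
    }
    stop("each phase must be a phase_params object or a list with $dG")
  })
  per_df <- data.frame(
    phase_label = vapply(per, `[[`, character(1), "phase_label"),
    dG = vapply(per, `[[`, numeric(1), "dG"),
    m_eq = vapply(per, `[[`, numeric(1), "m_eq"),
    se = vapply(per, function(p) as.numeric(p$se), numeric(1)),
    stringsAsFactors = FALSE)

  dG_eq <- abs(eq$dG)
  se_eq <- if (!is.null(eq$se) && "dG" %in% names(eq$se))
    eq$se[["dG"]] else NA_real_
  m_eq_titr <- if (!is.null(eq$m)) eq$m else NA_real_

  finite <- is.finite(per_df$dG)
  total <- sum(per_df$dG[finite])
  sum_mag <- sum(abs(per_df$dG[finite]))
  ses <- c(per_df$se[finite], se_eq)
  combined_se <- if (any(is.finite(ses))) sqrt(sum(ses[is.finite(ses)]^2))
                 else 0
  tolerance <- if (is.null(tol)) max(2 * combined_se, 0.5) else tol

  notes <- character()
  if (sum(finite) < 2L) {
    verdict <- "ambiguous"
    notes <- c(notes, "single-phase evidence")
  } else {
    d_sum <- abs(sum_mag - dG_eq)
    d_i <- abs(abs(per_df$dG[finite]) - dG_eq)
    single_better <- any(d_i <= tolerance & d_i < d_sum)
    if (d_sum <= tolerance && !single_better) {
      verdict <- "on_pathway"
    } else if (d_sum > tolerance && any(d_i <= tolerance)) {
      verdict <- "off_pathway"
      notes <- c(notes, "one step alone matches the equilibrium stability")
    } else {
      verdict <- "ambiguous"
      if (d_sum <= tolerance)
        notes <- c(notes, "both the sum and a single step match within tolerance")
    }
  }

  structure(
    list(per_phase = per_df,
         total_dG_kinetic = total,
         dG_equilibrium = dG_eq,
         m_eq_kinetic_total = sum(per_df$m_eq[is.finite(per_df$m_eq)]),
         m_equilibrium = m_eq_titr,
         verdict = verdict,
         tolerance_used = tolerance,
         notes = notes),
    class = "pathway_report"
  )
}

#' @export
print.pathway_report <- function(x, ...) {
  cat("Pathway report\n")
  for (i in seq_len(nrow(x$per_phase)))
    cat(sprintf("  %s phase: dG = %.3g kcal/mol, m_eq = %.3g kcal/mol/M\n",
                x$per_phase$phase_label[i], x$per_phase$dG[i],
                x$per_phase$m_eq[i]))
  cat(sprintf("  total kinetic dG = %.3g kcal/mol (sum of magnitudes %.3g)\n",
              x$total_dG_kinetic, sum(abs(x$per_phase$dG), na.rm = TRUE)))
  cat(sprintf("  equilibrium dG   = %.3g kcal/mol\n", x$dG_equilibrium))
  cat(sprintf("  verdict: %s (tolerance %.3g kcal/mol)\n",
              x$verdict, x$tolerance_used))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Screen a slow phase for proline cis-trans isomerisation
#'
#' Proline isomerisation produces slow phases with characteristic
#' signatures: rates on the 10-100 s timescale (0.01-0.1 1/s) and
#' essentially no denaturant dependence (a flat, not V-shaped, rate
#' profile). The flag is TRUE only when both hold: the rate at the
#' chevron minimum lies in \[0.01, 0.1\] 1/s and the phase's equilibrium
#' m-value is below 0.1 kcal/mol/M.
#'
#' @param p A [phase_params()].
#' @param rt Thermal energy RT in kcal/mol.
#' @return List with logical `flag` and free-text `rationale`.
#' @export
proline_flag <- function(p, rt = .RT) {
  stopifnot(inherits(p, "phase_params"))
  m_eq <- m_eq_from_kinetic(p$mf, p$mu)
  k_min <- if (p$mf > 0 && p$mu > 0) chevron_minimum(p, rt)$rate
           else chevron_rate(0, p, rt)
  slow_enough <- k_min >= 0.01 && k_min <= 0.1
  flat <- m_eq < 0.1
  flag <- slow_enough && flat
  rationale <- sprintf(
    "rate at chevron minimum %.3g /s (%s 10-100 s isomerisation window); m_eq %.3g kcal/mol/M (%s)",
    k_min, if (slow_enough) "inside" else "outside",
    m_eq, if (flat) "denaturant-independent" else "denaturant-dependent, V-shaped")
  list(flag = flag, rationale = rationale)
}
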