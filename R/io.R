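# Shared CSV machinery: files may begin with "# key=value" metadata lines,
# followed by a header row and numeric columns. Values are written with 15
# significant digits so a write -> read round trip is an identity up to
# float formatting.

.read_csv_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1, nchar(kv)))
  }
  body <- lines[!is_meta]
  if (length(body) < 2L) stop("no data rows in ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = "character", check.names = FALSE)
  list(meta = meta, df = df)
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing column(s) ", paste(sQuote(missing), collapse = ", "),
         " in ", path)
}

.numeric_column <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
  if (length(bad) || anyNA(v))
    stop("non-numeric value in column '", col, "' at data row ",
         if (length(bad)) bad[1] else which(is.na(v))[1], " of ", path)
  v
}

.fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Read / write titration CSV files
#'
#' Format: optional `# label=...` metadata line, then columns
#' `denaturant_M,signal`.
#'
#' @param path File path.
#' @return `read_titration_csv`: a [titration_curve()].
#' @export
read_titration_csv <- function(path) {
  r <- .read_csv_meta(path)
  .require_columns(r$df, c("denaturant_M", "signal"), path)
  titration_curve(.numeric_column(r$df, "denaturant_M", path),
                  .numeric_column(r$df, "signal", path),
                  label = if (!is.null(r$meta$label)) r$meta$label else "")
}

#' @rdname read_titration_csv
#' @param curve A [titration_curve()].
#' @export
write_titration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  lines <- c(
    if (nzchar(curve$label)) paste0("# label=", curve$label),
    "denaturant_M,signal",
    paste(.fmt(curve$denaturant), .fmt(curve$signal), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write stopped-flow trace CSV files
#'
#' Format: metadata lines `# denaturant_M=`, `# direction=`,
#' `# dead_time_s=`, then columns `time_s,signal`.
#'
#' @param path File path.
#' @return `read_trace_csv`: a [kinetic_trace()]; points inside the dead
#'   time are flagged excluded.
#' @export
read_trace_csv <- function(path) {
  r <- .read_csv_meta(path)
  .require_columns(r$df, c("time_s", "signal"), path)
  if (is.null(r$meta$denaturant_M))
    stop("missing metadata line '# denaturant_M=' in ", path)
  kinetic_trace(
    .numeric_column(r$df, "time_s", path),
    .numeric_column(r$df, "signal", path),
    denaturant_final = as.numeric(r$meta$denaturant_M),
    direction = if (!is.null(r$meta$direction)) r$meta$direction else "folding",
    dead_time = if (!is.null(r$meta$dead_time_s))
      as.numeric(r$meta$dead_time_s) else 0.0034)
}

#' @rdname read_trace_csv
#' @param trace A [kinetic_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  lines <- c(
    paste0("# denaturant_M=", .fmt(trace$denaturant_final)),
    paste0("# direction=", trace$direction),
    paste0("# dead_time_s=", .fmt(trace$dead_time)),
    "time_s,signal",
    paste(.fmt(trace$time), .fmt(trace$signal), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write chevron CSV files
#'
#' Format: optional `# protein=` metadata line, then columns
#' `denaturant_M,k_obs_per_s,phase` with phase in fast/slow.
#'
#' @param path File path.
#' @return `read_chevron_csv`: a [chevron_dataset()].
#' @export
read_chevron_csv <- function(path) {
  r <- .read_csv_meta(path)
  .require_columns(r$df, c("denaturant_M", "k_obs_per_s", "phase"), path)
  chevron_dataset(
    .numeric_column(r$df, "denaturant_M", path),
    .numeric_column(r$df, "k_obs_per_s", path),
    r$df$phase,
    protein = if (!is.null(r$meta$protein)) r$meta$protein else "")
}

#' @rdname read_chevron_csv
#' @param data A [chevron_dataset()].
#' @export
write_chevron_csv <- function(data, path) {
  stopifnot(inherits(data, "chevron_dataset"))
  lines <- c(
    if (nzchar(data$protein)) paste0("# protein=", data$protein),
    "denaturant_M,k_obs_per_s,phase",
    paste(.fmt(data$points$denaturant), .fmt(data$points$rate),
          data$points$phase, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full folding-analysis pipeline
#'
#' Orchestrates the analysis chain: equilibrium fit, per-trace
#' exponential fits with phase-count selection, chevron assembly,
#' per-branch chevron fits, and pathway classification. Inputs come
#' either from files named in the config or from the synthetic generator
#' driven by a named preset; all randomness is controlled by the config
#' seed, so reruns with the same config are identical.
#'
#' The config is a named list (or path to a YAML file) with components:
#' \describe{
#'   \item{preset}{"CCL11" or "CCL24" for simulated input. In simulated
#'     mode the titration truth is the preset scheme's own total free
#'     energy and m-value, so the generated world is thermodynamically
#'     self-consistent.}
#'   \item{scheme}{a [three_state_scheme()] for simulated input from a
#'     custom ground truth (e.g. [validation_scheme()]); alternative to
#'     `preset`.}
#'   \item{inputs}{alternatively, list with `titration` (path) and either
#'     `traces` (character vector of paths) or `chevron` (path).}
#'   \item{seed}{integer, default 0.}
#'   \item{noise}{optional list overriding [noise_spec()] fields.}
#'   \item{denaturant_grid}{simulation trace concentrations (M), default
#'     0.25 to 7 M in 0.25 M steps.}
#'   \item{tolerance}{optional pathway tolerance (kcal/mol).}
#'   \item{output_dir}{optional; when set, writes `parameters.csv` and
#'     `summary.txt` (plus the simulated inputs in simulated mode).}
#'   \item{verbose}{logical, default FALSE; progress messages to stderr.}
#' }
#'
#' @param config Named list or path to a YAML config file.
#' @return A list of class `pipeline_result` with `equilibrium`
#'   ([two_state_fit()]), `trace_fits`, `chevron` ([chevron_dataset()]),
#'   `phases` (list of [phase_params()]), `report`
#'   ([classify_pathway()] result) and `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 0L
  verbose <- isTRUE(config$verbose)
  noise_args <- config$noise
  noise <- do.call(noise_spec, c(noise_args[setdiff(names(noise_args), "seed")],
                                 list(seed = seed)))

  simulated <- !is.null(config$preset) || !is.null(config$scheme)
  if (!simulated &&
      (is.null(config$inputs) || is.null(config$inputs$titration) ||
       (is.null(config$inputs$traces) && is.null(config$inputs$chevron))))
    stop("configuration error: supply either 'preset' or 'inputs' with ",
         "'titration' plus 'traces' or 'chevron'")

  traces <- NULL; chev <- NULL
  if (simulated) {
    if (!is.null(config$scheme)) {
      stopifnot(inherits(config$scheme, "three_state_scheme"))
      scheme <- config$scheme
      sim_label <- "scheme"
    } else {
      preset <- ccl_preset(config$preset)
      scheme <- preset$scheme
      sim_label <- preset$protein
    }
    fe <- scheme_free_energies(scheme)
    fk_log(verbose, "simulating %s: titration (dG=%.2f, m=%.2f), seed %d",
           sim_label, abs(fe$total), fe$m_total, seed)
    curve <- simulate_titration(
      dG = abs(fe$total), m = fe$m_total,
      noise = noise_spec(titration_sd = noise$titration_sd,
                         seed = seed),
      label = sim_label)
    grid <- if (!is.null(config$denaturant_grid))
      as.numeric(config$denaturant_grid) else seq(0.25, 7, by = 0.25)
    d50 <- abs(fe$total) / fe$m_total
    n_rep <- if (!is.null(config$n_replicates))
      as.integer(config$n_replicates) else 3L
    # both folding and unfolding jumps at every final concentration; the
    # species amplitudes decide which phases are observable where
    cond <- expand.grid(x = grid, dir = c("folding", "unfolding"),
                        stringsAsFactors = FALSE)
    traces <- lapply(seq_len(nrow(cond)), function(i) {
      x <- cond$x[i]; dir <- cond$dir[i]
      # stopped-flow shots are repeated and averaged; replicate traces
      # share the time grid, so averaging the signals is exact
      reps <- lapply(seq_len(n_rep), function(r)
        simulate_trace(
          scheme, x, direction = dir,
          noise = noise_spec(
            trace_sd = noise$trace_sd,
            seed = (seed + 7919L * i + 104729L * r) %% .Machine$integer.max)))
      avg <- rowMeans(vapply(reps, `[[`, numeric(length(reps[[1]]$time)),
                             "signal"))
      kinetic_trace(reps[[1]]$time, avg, denaturant_final = x,
                    direction = dir)
    })
  } else {
    curve <- read_titration_csv(config$inputs$titration)
    if (!is.null(config$inputs$traces))
      traces <- lapply(config$inputs$traces, read_trace_csv)
    else
      chev <- read_chevron_csv(config$inputs$chevron)
  }

  fk_log(verbose, "stage 1/4: equilibrium two-state fit (%d points)",
         length(curve$denaturant))
  eq_fit <- tryCatch(fit_two_state(curve),
                     error = function(e)
                       stop("equilibrium_fit stage failed (",
                            curve$label, "): ", conditionMessage(e)))

  trace_fits <- NULL
  if (!is.null(traces)) {
    fk_log(verbose, "stage 2/4: fitting %d stopped-flow traces", length(traces))
    trace_fits <- lapply(traces, function(tr) {
      sel <- tryCatch(select_phase_count(tr),
                      error = function(e)
                        stop("kinetics_fit stage failed (trace at ",
                             tr$denaturant_final, " M): ", conditionMessage(e)))
      list(denaturant = tr$denaturant_final, fit = sel)
    })
    # drop traces whose relaxation amplitude is lost in the noise: their
    # fitted rates carry no information
    usable <- vapply(trace_fits, function(f) {
      ft <- f$fit$fit
      np <- attr(ft, "n_points")
      if (is.null(np)) np <- 100L
      noise_sd <- sqrt(ft$residual_sse / np)
      sum(abs(ft$amplitudes)) > 5 * noise_sd && !("no relaxation" %in% ft$flags)
    }, logical(1))
    dead <- max(vapply(traces, `[[`, numeric(1), "dead_time"))
    span <- max(vapply(traces, function(tr) max(tr$time), numeric(1)))
    chev <- assemble_chevron(trace_fits[usable],
                             protein = if (simulated) sim_label else "",
                             max_rate = 0.5 / max(dead, 1e-6),
                             min_rate = 0.5 / span)
  }

  fk_log(verbose, "stage 3/4: chevron fits")
  phases <- list()
  for (ph in c("fast", "slow")) {
    np <- sum(chev$points$phase == ph)
    if (np >= 6L) {
      phases[[ph]] <- tryCatch(fit_chevron_phase(chev, ph),
                               error = function(e)
                                 stop("chevron_fit stage failed (", ph,
                                      " branch): ", conditionMessage(e)))
    } else {
      fk_log(verbose, "  %s branch: %d point(s), skipped (need >= 6)", ph, np)
    }
  }
  if (length(phases) == 0L)
    stop("chevron_fit stage failed: no branch has enough points")

  fk_log(verbose, "stage 4/4: pathway classification")
  # a branch fitted over a single limb extrapolates the opposing rate
  # constant over molar distances; its step free energy is unusable
  reliable <- Filter(function(p) !any(grepl("ill-constrained", p$flags)),
                     phases)
  excluded <- setdiff(names(phases), vapply(reliable, `[[`, "", "phase_label"))
  report <- classify_pathway(
    if (length(reliable)) unname(reliable) else unname(phases),
    eq_fit, tol = config$tolerance)
  if (length(excluded) && length(reliable))
    report$notes <- c(report$notes,
                      paste0("phase(s) excluded as ill-constrained: ",
                             paste(excluded, collapse = ", ")))

  out <- structure(
    list(equilibrium = eq_fit, trace_fits = trace_fits, chevron = chev,
         phases = phases, report = report, config = config),
    class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(out, config$output_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Folding-analysis pipeline result\n\n")
  print(x$equilibrium)
  cat("\n")
  for (p in x$phases) print(p)
  cat("\n")
  print(x$report)
  invisible(x)
}

# Flat parameter CSV + human-readable summary under `dir`.
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eq <- result$equilibrium
  rows <- data.frame(
    stage = "equilibrium",
    parameter = c("a_N", "b_N", "a_D", "b_D", "m", "D50", "dG"),
    value = c(eq$a_N, eq$b_N, eq$a_D, eq$b_D, eq$m, eq$D50, eq$dG),
    stringsAsFactors = FALSE)
  for (p in result$phases) {
    rows <- rbind(rows, data.frame(
      stage = paste0("chevron_", p$phase_label),
      parameter = c("kf0", "mf", "ku0", "mu"),
      value = c(p$kf0, p$mf, p$ku0, p$mu), stringsAsFactors = FALSE))
  }
  rep <- result$report
  rows <- rbind(rows, data.frame(
    stage = "pathway",
    parameter = c("total_dG_kinetic", "dG_equilibrium", "tolerance_used"),
    value = c(rep$total_dG_kinetic, rep$dG_equilibrium, rep$tolerance_used),
    stringsAsFactors = FALSE))
  utils::write.csv(rows, file.path(dir, "parameters.csv"), row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); print(result); sink()
  close(con)
  invisible(dir)
}
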