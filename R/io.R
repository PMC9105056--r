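#' Read / write the cohort tables
#'
#' The pipeline exchanges two delimited tables: `subjects.csv` (one row
#' per subject, columns as in [simulate_cohort()]'s `subjects`) and
#' `bat_long.csv` (one row per well: `subject_id`, `allergen`, `marker`,
#' `background_pct`, `concentration`, `activation_pct`).  Readers
#' validate the schema and percent ranges; unknown columns are preserved.
#' Writing then reading reproduces values exactly (full-precision
#' formatting).
#'
#' @param path file path.
#' @return `read_bat_long()` / `read_subjects()` return validated data
#'   frames; the writers return the path invisibly.
#' @name bat_io
NULL

required_bat_cols <- c("subject_id", "allergen", "marker", "background_pct",
                       "concentration", "activation_pct")
required_subject_cols <- c("subject_id", "cohort", "severity", "peanut_group",
                           "profilin_sensitized", "age", "sex", "total_ige",
                           "sige_prup3", "sige_arah9", "spt_peach_area",
                           "spt_peanut_area")

check_cols <- function(d, required, path) {
  miss <- setdiff(required, names(d))
  if (length(miss))
    input_error("schema error in '", path, "': missing required column(s) ",
                paste(miss, collapse = ", "))
}

check_pct <- function(d, col, path) {
  bad <- which(is.na(d[[col]]) | d[[col]] < 0 | d[[col]] > 100)
  if (length(bad))
    input_error("validation error in '", path, "': '", col,
                "' outside [0, 100] at data row(s) ",
                paste(utils::head(bad, 5), collapse = ", "))
}

#' @rdname bat_io
#' @export
read_bat_long <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(d, required_bat_cols, path)
  if (nrow(d) == 0) {
    warning("'", path, "' contains headers but no rows")
    return(d)
  }
  check_pct(d, "activation_pct", path)
  check_pct(d, "background_pct", path)
  if (any(d$concentration <= 0))
    input_error("validation error in '", path,
                "': nonpositive concentration")
  d
}

#' @rdname bat_io
#' @export
read_subjects <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(d, required_subject_cols, path)
  if (nrow(d) == 0) {
    warning("'", path, "' contains headers but no rows")
    return(d)
  }
  d$peanut_group[d$peanut_group %in% c("", "NA")] <- NA_character_
  d$profilin_sensitized <- as.logical(d$profilin_sensitized)
  for (col in c("total_ige", "sige_prup3", "sige_arah9",
                "spt_peach_area", "spt_peanut_area"))
    if (any(d[[col]] < 0))
      input_error("validation error in '", path, "': negative '", col, "'")
  d
}

#' @rdname bat_io
#' @param cohort a `bat_cohort` object from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "subjects.csv")
  bp <- file.path(dir, "bat_long.csv")
  utils::write.csv(format(cohort$subjects, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   sp, row.names = FALSE, quote = FALSE)
  bat <- cohort$bat
  bat$concentration <- format(bat$concentration, digits = 17, trim = TRUE)
  bat$background_pct <- format(bat$background_pct, digits = 17, trim = TRUE)
  bat$activation_pct <- format(bat$activation_pct, digits = 17, trim = TRUE)
  utils::write.csv(bat, bp, row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a simulation configuration from YAML
#'
#' Key/value (nestable) text configuration for [simulate_cohort()];
#' unspecified fields fall back to the [bat_sim_config()] defaults.
#'
#' @param path YAML file.
#' @return a `bat_sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(bat_sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    input_error("configuration error: unknown field(s) ",
                paste(unknown, collapse = ", "))
  if (!is.null(raw$profilin_probs)) raw$profilin_probs <- unlist(raw$profilin_probs)
  do.call(bat_sim_config, raw)
}

#' Run the whole BAT diagnostic pipeline
#'
#' Orchestrates the full analysis in study order: (optional) cohort
#' simulation -> nonresponder flagging and curve fits -> selection of the
#' discriminating concentrations -> ROC cut-off derivation (or the bundled
#' reference cut-offs) -> per-subject positivity calls and group
#' positivity rates -> cohort summary and group comparisons -> PCA.
#' Fully deterministic given the seed.
#'
#' @param subjects,bat input tables; if both `NULL`, a cohort is
#'   simulated from `sim_config`.
#' @param sim_config a [bat_sim_config()]; its seed is overridden by
#'   `seed` when given.
#' @param seed integer seed controlling all randomness.
#' @param k_concentrations how many discriminating concentrations to
#'   select (default 3).
#' @param cutoff_source `"derived"` (ROC on this cohort) or `"reference"`
#'   (bundled published thresholds; skips ROC derivation).
#' @param marker marker for the positivity analysis (default `"CD63"`).
#' @param min_peak,fold_over_background responder-rule thresholds.
#' @param out_dir optional directory; when given, all result tables are
#'   written as CSV (`fits.csv`, `cutoffs.csv`, `calls.csv`,
#'   `positivity.csv`, `table1.csv`, `scores.csv`, `loadings.csv`).
#' @return list of class `bat_pipeline` with `subjects`, `bat`, `fits`,
#'   `selected_concentrations`, `cutoffs`, `calls`, `positivity`,
#'   `summary`, `pca`.
#' @export
run_pipeline <- function(subjects = NULL, bat = NULL,
                         sim_config = bat_sim_config(), seed = NULL,
                         k_concentrations = 3,
                         cutoff_source = c("derived", "reference"),
                         marker = "CD63", min_peak = 5,
                         fold_over_background = 2, out_dir = NULL) {
  cutoff_source <- match.arg(cutoff_source)
  if (is.null(subjects) != is.null(bat))
    input_error("run_pipeline: supply both 'subjects' and 'bat', or neither")
  if (is.null(subjects)) {
    if (!is.null(seed)) sim_config$seed <- seed
    coh <- simulate_cohort(sim_config)
    subjects <- coh$subjects; bat <- coh$bat
  }

  fits <- fit_cohort(bat, min_peak = min_peak,
                     fold_over_background = fold_over_background)
  sel <- select_discriminating_concentrations(bat, subjects,
                                              k = k_concentrations,
                                              marker = marker)
  cutoffs <- if (cutoff_source == "reference") reference_cutoffs()
             else derive_cutoffs(bat, subjects,
                                 concentrations = sel)
  calls <- classify_cohort(bat, cutoffs, marker = marker,
                           concentrations = intersect(sort(cutoffs$concentration[
                             cutoffs$marker == marker]), bat$concentration))
  pos <- rbind(positivity_rate(calls, subjects, "cohort"),
               positivity_rate(calls, subjects, "severity"))
  summary <- summarize_cohort(subjects)
  feats <- bat_feature_table(subjects, bat, fits,
                             concentration = max(sel))
  pca <- run_pca(feats)

  out <- structure(list(subjects = subjects, bat = bat, fits = fits,
                        selected_concentrations = sel, cutoffs = cutoffs,
                        calls = calls, positivity = pos, summary = summary,
                        pca = pca),
                   class = "bat_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                         row.names = FALSE)
    w(fits, "fits.csv"); w(cutoffs, "cutoffs.csv"); w(calls, "calls.csv")
    w(pos, "positivity.csv"); w(summary$groups, "table1.csv")
    w(data.frame(subject_id = rownames(pca$scores), pca$scores), "scores.csv")
    w(data.frame(feature = rownames(pca$loadings), pca$loadings),
      "loadings.csv")
  }
  out
}

#' @export
print.bat_pipeline <- function(x, ...) {
  cat("BAT pipeline:", nrow(x$subjects), "subjects;",
      "selected concentrations:",
      paste(format(x$selected_concentrations, scientific = TRUE),
            collapse = ", "), "\n")
  cat("Positivity by group:\n"); print(x$positivity)
  invisible(x)
}
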