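#' Principal component analysis of subject-level BAT features
#'
#' Centred (and by default unit-variance-scaled) PCA via singular value
#' decomposition of the feature table, as used to visualise whether the
#' combination of serology, skin testing and BAT readouts separates
#' allergic subjects from controls.  Rows with any missing feature (e.g.
#' undefined CD-sens in nonresponders) are dropped and reported.
#' Component signs are fixed deterministically by making the
#' largest-magnitude loading of each component positive.
#'
#' @param feature_table numeric data frame or matrix, subjects x features
#'   (>= 2 of each); row names identify subjects.
#' @param standardize `"unit-variance"` (default) or `"none"` (centring
#'   only).
#' @return list of class `bat_pca`: `features`, `standardize`, `loadings`
#'   (features x components, orthonormal), `scores` (subjects x
#'   components, zero mean), `explained_variance_pct` (nonincreasing,
#'   sums to 100), `dropped` (row names removed for missingness).
#' @export
run_pca <- function(feature_table, standardize = c("unit-variance", "none")) {
  standardize <- match.arg(standardize)
  X <- as.matrix(feature_table)
  if (!is.numeric(X)) input_error("run_pca: features must be numeric")
  keep <- stats::complete.cases(X)
  dropped <- rownames(X)[!keep]
  if (length(dropped))
    message("run_pca: dropping ", length(dropped),
            " row(s) with missing features")
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 2 || ncol(X) < 2)
    input_error("run_pca: need at least 2 complete subjects and 2 features")
  sds <- apply(X, 2, stats::sd)
  if (standardize == "unit-variance" && any(sds == 0))
    input_error("run_pca: constant feature(s) under unit-variance scaling: ",
                paste(colnames(X)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE,
                      scale. = (standardize == "unit-variance"))
  # deterministic sign: largest-|loading| entry of each component positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ev <- pc$sdev^2
  structure(list(features = colnames(X),
                 standardize = standardize,
                 loadings = loadings,
                 scores = scores,
                 explained_variance_pct = 100 * ev / sum(ev),
                 dropped = dropped),
            class = "bat_pca")
}

#' @export
print.bat_pca <- function(x, ...) {
  cat("PCA of", length(x$features), "features,", nrow(x$scores),
      "subjects (", x$standardize, "scaling )\n")
  ev <- round(x$explained_variance_pct, 1)
  cat("Explained variance (%):", paste(ev, collapse = ", "), "\n")
  invisible(x)
}

#' Build the PCA feature table for a cohort
#'
#' Assembles the subject-level features used for multivariate views of the
#' cohort: specific IgE to Pru p 3 (log10(x + 0.01)-transformed — serum
#' IgE is heavily right-skewed), the two BAT reactivity readouts at a
#' chosen concentration, and optionally the SPT peach wheal area, curve
#' AUC and CD-sens from the dose-response fits.
#'
#' @param subjects subject metadata.
#' @param bat long-format BAT table.
#' @param fits optional output of [fit_cohort()]; required for the
#'   `curve_auc` / `cd_sens` features.
#' @param concentration concentration at which reactivity is taken
#'   (default 0.1 ug/mL).
#' @param features which features to include.
#' @param allergen allergen (default `"PRU_P_3"`).
#' @param log_sige log10-transform sIgE (default TRUE).
#' @return numeric data frame, subjects as row names.
#' @export
bat_feature_table <- function(subjects, bat, fits = NULL,
                              concentration = 0.1,
                              features = c("sige_prup3", "cd63", "cd203c"),
                              allergen = "PRU_P_3", log_sige = TRUE) {
  out <- data.frame(row.names = subjects$subject_id)
  react <- function(marker) {
    d <- bat[bat$marker == marker & bat$allergen == allergen &
               bat$concentration == concentration, ]
    d$activation_pct[match(subjects$subject_id, d$subject_id)]
  }
  fitcol <- function(col, marker = "CD63") {
    if (is.null(fits)) input_error("bat_feature_table: 'fits' needed for ", col)
    d <- fits[fits$marker == marker & fits$allergen == allergen, ]
    d[[col]][match(subjects$subject_id, d$subject_id)]
  }
  for (f in features) {
    out[[f]] <- switch(f,
      sige_prup3 = if (log_sige) log10(subjects$sige_prup3 + 0.01)
                   else subjects$sige_prup3,
      cd63 = react("CD63"),
      cd203c = react("CD203c"),
      spt_peach = subjects$spt_peach_area,
      curve_auc = fitcol("curve_auc"),
      cd_sens = log10(fitcol("cd_sens")),
      input_error("bat_feature_table: unknown feature '", f, "'"))
  }
  out
}
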