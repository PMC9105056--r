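#' Empirical ROC curve for a BAT readout
#'
#' Computes the empirical receiver operating characteristic of percent
#' activation as a marker of allergy, under the orientation "allergic
#' subjects have higher activation".  Candidate thresholds are the
#' midpoints between consecutive distinct pooled values, plus sentinels
#' below the minimum and above the maximum.  At a threshold t,
#' sensitivity is the percentage of allergic values strictly above t and
#' specificity the percentage of control values at or below t.
#'
#' @param values_allergic,values_control percent activation in each cohort
#'   (both nonempty).
#' @return data frame of class `bat_roc` with columns `threshold`,
#'   `sensitivity`, `specificity` (percent), ordered by threshold, plus
#'   attributes `n_allergic`, `n_control`.
#' @export
roc_curve <- function(values_allergic, values_control) {
  if (length(values_allergic) == 0 || length(values_control) == 0)
    input_error("roc_curve: both cohorts must be nonempty")
  pooled <- sort(unique(c(values_allergic, values_control)))
  thr <- c(pooled[1] - 1,
           if (length(pooled) > 1) (utils::head(pooled, -1) + utils::tail(pooled, -1)) / 2,
           pooled[length(pooled)] + 1)
  sens <- vapply(thr, function(t) 100 * mean(values_allergic > t), numeric(1))
  spec <- vapply(thr, function(t) 100 * mean(values_control <= t), numeric(1))
  out <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  attr(out, "n_allergic") <- length(values_allergic)
  attr(out, "n_control") <- length(values_control)
  class(out) <- c("bat_roc", "data.frame")
  out
}

#' ROC area under the curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen allergic value exceeds a
#' randomly chosen control value, with ties counted one half — the
#' Mann-Whitney U statistic scaled to \[0, 1\], which equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(2, 4), c(1, 3))  # 0.75
#' @export
roc_auc <- function(values_allergic, values_control) {
  if (length(values_allergic) == 0 || length(values_control) == 0)
    input_error("roc_auc: both cohorts must be nonempty")
  n1 <- length(values_allergic); n2 <- length(values_control)
  r <- rank(c(values_allergic, values_control))   # midranks handle ties as 1/2
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Optimal diagnostic cut-off from a ROC curve
#'
#' Selects the threshold maximising Youden's J (sensitivity + specificity
#' - 100), breaking ties by larger specificity and then by larger
#' threshold.  Positive and negative predictive values are computed from
#' the confusion counts at the observed cohort composition (prevalence =
#' n_allergic / total).  The alternative `criterion = "accuracy"`
#' maximises overall accuracy instead.
#'
#' @param curve a `bat_roc` object from [roc_curve()].
#' @param criterion `"youden"` (default) or `"accuracy"`.
#' @return one-row data frame: `cutoff`, `roc_auc`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `youden_j`, `informative` (FALSE when
#'   the best J is 0, i.e. the readout carries no diagnostic signal).
#' @export
optimal_cutoff <- function(curve, criterion = c("youden", "accuracy")) {
  criterion <- match.arg(criterion)
  if (nrow(curve) == 0) input_error("optimal_cutoff: empty ROC curve")
  n1 <- attr(curve, "n_allergic"); n2 <- attr(curve, "n_control")
  score <- switch(criterion,
    youden = curve$sensitivity + curve$specificity - 100,
    accuracy = (curve$sensitivity * n1 + curve$specificity * n2) / (n1 + n2))
  ord <- order(-score, -curve$specificity, -curve$threshold)
  i <- ord[1]
  tp <- curve$sensitivity[i] / 100 * n1
  fn <- n1 - tp
  tn <- curve$specificity[i] / 100 * n2
  fp <- n2 - tn
  auc <- sum(-diff(1 - curve$specificity / 100) *
             (utils::head(curve$sensitivity, -1) +
              utils::tail(curve$sensitivity, -1)) / 200)
  data.frame(
    cutoff = curve$threshold[i],
    roc_auc = auc,
    sensitivity = curve$sensitivity[i],
    specificity = curve$specificity[i],
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_,
    youden_j = curve$sensitivity[i] + curve$specificity[i] - 100,
    informative = (curve$sensitivity[i] + curve$specificity[i] - 100) > 0)
}

#' Derive ROC cut-offs per marker and concentration
#'
#' For each requested marker x concentration, compares allergic versus
#' control activation and returns the ROC AUC, the optimal cut-off and its
#' accuracy metrics.
#'
#' @param bat long-format BAT table.
#' @param subjects subject metadata (`subject_id`, `cohort`).
#' @param markers markers to evaluate (default both readouts).
#' @param concentrations concentrations to evaluate (default: all in
#'   `bat`).
#' @param allergen allergen to evaluate (default `"PRU_P_3"`).
#' @param criterion passed to [optimal_cutoff()].
#' @return data frame, one row per marker x concentration, with
#'   `marker`, `concentration`, `roc_auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`.
#' @export
derive_cutoffs <- function(bat, subjects, markers = unique(bat$marker),
                           concentrations = NULL, allergen = "PRU_P_3",
                           criterion = "youden") {
  if (is.null(concentrations))
    concentrations <- sort(unique(bat$concentration))
  cohort <- subjects$cohort[match(bat$subject_id, subjects$subject_id)]
  rows <- list(); k <- 0L
  for (mk in markers) for (cc in concentrations) {
    sel <- bat$marker == mk & bat$allergen == allergen &
      bat$concentration == cc
    va <- bat$activation_pct[sel & cohort == "ALLERGIC"]
    vc <- bat$activation_pct[sel & cohort == "CONTROL"]
    oc <- optimal_cutoff(roc_curve(va, vc), criterion = criterion)
    k <- k + 1L
    rows[[k]] <- cbind(data.frame(marker = mk, concentration = cc), oc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published reference cut-offs for BAT to Pru p 3
#'
#' Cut-off values (percent activation) reported for the two BAT readouts
#' at the three highest Pru p 3 concentrations, together with the
#' published ROC AUC and accuracy metrics.  These are bundled as reference
#' constants for applying the published thresholds to new data; they are
#' cohort-dependent and are not recomputable from this package's synthetic
#' cohorts.
#'
#' @return data frame with `marker`, `concentration`, `roc_auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
reference_cutoffs <- function() {
  data.frame(
    marker = rep(c("CD63", "CD203c"), each = 3),
    concentration = rep(c(0.1, 0.01, 0.001), 2),
    roc_auc = c(0.947, 0.938, 0.914, 1, 0.973, 0.951),
    cutoff = c(12.35, 5.87, 6.605, 9.96, 17.25, 9.655),
    sensitivity = c(85.26, 92.05, 85.06, 100, 80.48, 92.06),
    specificity = c(93.75, 87.50, 93.75, 100, 100, 100),
    ppv = c(100, 97.8, 98.7, 100, 100, 100),
    npv = c(100, 100, 53.6, 100, 71.4, 75.0))
}

#' BAT positivity call for one subject
#'
#' A subject is BAT-positive for a marker when the activation exceeds the
#' concentration-specific cut-off (strictly) at two or more consecutive
#' concentrations among those evaluated, in ascending concentration order.
#'
#' @param activation_pct activation at each evaluated concentration
#'   (ascending order).
#' @param cutoffs cut-off per evaluated concentration, same length.
#' @return list with `positive` (logical) and `exceeded` (logical vector).
#' @examples
#' classify_subject(c(2, 7, 8), c(5, 5, 5))$positive  # TRUE
#' classify_subject(c(7, 2, 8), c(5, 5, 5))$positive  # FALSE
#' @export
classify_subject <- function(activation_pct, cutoffs) {
  if (length(activation_pct) != length(cutoffs))
    input_error("classify_subject: activation and cutoff lengths differ")
  if (anyNA(activation_pct))
    input_error("classify_subject: missing measurement at evaluated ",
                "concentration(s) ", paste(which(is.na(activation_pct)),
                                           collapse = ", "))
  exceeded <- activation_pct > cutoffs
  list(positive = longest_true_run(exceeded) >= 2, exceeded = exceeded)
}

#' BAT positivity calls for a cohort
#'
#' Applies [classify_subject()] per subject for one marker over the
#' evaluated concentrations, using a cut-off table (derived or reference).
#'
#' @param bat long-format BAT table.
#' @param cutoffs data frame with `marker`, `concentration`, `cutoff`.
#' @param marker marker to classify on.
#' @param concentrations concentrations to evaluate, ascending; default
#'   all concentrations present in `cutoffs` for that marker.
#' @param allergen allergen (default `"PRU_P_3"`).
#' @return data frame, one row per subject: `subject_id`, `marker`,
#'   `positive`, plus one `exceeded_<concentration>` column per evaluated
#'   concentration.
#' @export
classify_cohort <- function(bat, cutoffs, marker = "CD63",
                            concentrations = NULL, allergen = "PRU_P_3") {
  ct <- cutoffs[cutoffs$marker == marker, ]
  if (is.null(concentrations)) concentrations <- sort(ct$concentration)
  concentrations <- sort(concentrations)
  cut_at <- ct$cutoff[match(concentrations, ct$concentration)]
  if (anyNA(cut_at))
    input_error("classify_cohort: no cut-off for concentration(s) ",
                paste(concentrations[is.na(cut_at)], collapse = ", "))
  d <- bat[bat$marker == marker & bat$allergen == allergen &
             bat$concentration %in% concentrations, ]
  res <- lapply(split(d, d$subject_id), function(s) {
    s <- s[order(s$concentration), ]
    if (nrow(s) != length(concentrations))
      input_error("classify_cohort: subject ", s$subject_id[1],
                  " is missing measurement(s) at evaluated concentration(s) ",
                  paste(setdiff(concentrations, s$concentration),
                        collapse = ", "))
    cl <- classify_subject(s$activation_pct, cut_at)
    ex <- as.list(cl$exceeded)
    names(ex) <- paste0("exceeded_", format(concentrations, scientific = TRUE))
    cbind(data.frame(subject_id = s$subject_id[1], marker = marker,
                     positive = cl$positive, stringsAsFactors = FALSE),
          as.data.frame(ex))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Percent BAT-positive per group
#'
#' Summarises positivity calls by subject group, reporting the percentage
#' positive with its numerator and denominator.  Empty groups are reported
#' with `NA` percentage, not zero.
#'
#' @param calls output of [classify_cohort()].
#' @param subjects subject metadata.
#' @param grouping name of the grouping column in `subjects` (e.g.
#'   `"cohort"`, `"severity"`, `"peanut_group"`).
#' @return data frame: `group`, `n_positive`, `n`, `pct_positive`
#'   (round-half-up to 2 decimals).
#' @export
positivity_rate <- function(calls, subjects, grouping = "cohort") {
  g <- subjects[[grouping]][match(calls$subject_id, subjects$subject_id)]
  levs <- unique(subjects[[grouping]])
  levs <- levs[!is.na(levs)]
  out <- do.call(rbind, lapply(levs, function(lv) {
    sel <- !is.na(g) & g == lv
    p <- percentage(sum(calls$positive[sel]), sum(sel))
    data.frame(group = lv, n_positive = p$numerator, n = p$denominator,
               pct_positive = p$pct, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
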