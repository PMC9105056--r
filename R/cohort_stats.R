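#' Skin prick test positivity
#'
#' A wheal of 7 mm^2 or larger is positive.
#'
#' @param area_mm2 wheal area(s) in mm^2; must be >= 0.
#' @return logical vector.
#' @examples
#' spt_positive(c(6.99, 7, 52))  # FALSE TRUE TRUE
#' @export
spt_positive <- function(area_mm2) {
  if (any(area_mm2 < 0)) input_error("spt_positive: areas must be >= 0")
  area_mm2 >= 7
}

#' Oral food challenge dose schedule arithmetic
#'
#' Converts a schedule of administered volumes into per-dose and
#' cumulative allergen amounts.  E.g. a 5 mL starting dose of peach juice
#' at 6.2 mg Pru p 3 per mL delivers 31 mg; the full 250 mL cumulative
#' volume delivers 1550 mg.
#'
#' @param dose_volumes_ml administered volumes in mL, in order; all > 0.
#' @param mg_per_ml allergen concentration of the preparation, mg/mL; > 0.
#' @return data frame with `volume_ml`, `dose_mg`, `cumulative_mg`; empty
#'   schedule gives zero rows (cumulative 0).
#' @examples
#' ofc_cumulative_dose(c(5, 10, 35, 50, 50, 100), 6.2)
#' @export
ofc_cumulative_dose <- function(dose_volumes_ml, mg_per_ml) {
  if (mg_per_ml <= 0) input_error("ofc_cumulative_dose: concentration must be > 0")
  if (length(dose_volumes_ml) == 0)
    return(data.frame(volume_ml = numeric(0), dose_mg = numeric(0),
                      cumulative_mg = numeric(0)))
  if (any(dose_volumes_ml <= 0))
    input_error("ofc_cumulative_dose: volumes must be > 0")
  dose <- dose_volumes_ml * mg_per_ml
  data.frame(volume_ml = dose_volumes_ml, dose_mg = dose,
             cumulative_mg = cumsum(dose))
}

#' Cohort summary table
#'
#' Reproduces the standard clinical-cohort summary from raw subject
#' records: per group (controls, all allergic, each severity group) the
#' size, percent female, mean +/- SD age, median (Q1-Q3) of SPT wheal
#' areas and IgE levels, and percent profilin-sensitized; plus the derived
#' cohort-flow percentages (severity shares of the allergic population and
#' the peanut-tolerant Group A / peanut-allergic Group B split, with SPT
#' positivity within each).  All percentages are rounded half-up to two
#' decimals and carry their numerator and denominator.
#'
#' @param subjects subject metadata data frame (see [simulate_cohort()]).
#' @return list of class `bat_cohort_summary` with components `groups`
#'   (one row per group) and `derived` (named list of
#'   numerator/denominator percentages).
#' @export
summarize_cohort <- function(subjects) {
  if (nrow(subjects) == 0) input_error("summarize_cohort: no subjects")
  med_iqr <- function(x) sprintf("%.2f (%.2f-%.2f)",
                                 stats::median(x),
                                 stats::quantile(x, 0.25),
                                 stats::quantile(x, 0.75))
  one_group <- function(d, label) {
    data.frame(
      group = label,
      n = nrow(d),
      pct_female = percentage(sum(d$sex == "F"), nrow(d))$pct,
      age_mean = round_half_up(mean(d$age), 2),
      age_sd = round_half_up(stats::sd(d$age), 2),
      spt_peach = med_iqr(d$spt_peach_area),
      spt_peanut = med_iqr(d$spt_peanut_area),
      pct_profilin = percentage(sum(d$profilin_sensitized), nrow(d))$pct,
      total_ige = med_iqr(d$total_ige),
      sige_prup3 = med_iqr(d$sige_prup3),
      sige_arah9 = med_iqr(d$sige_arah9),
      stringsAsFactors = FALSE)
  }
  alg <- subjects[subjects$cohort == "ALLERGIC", ]
  grp <- list(one_group(subjects[subjects$cohort == "CONTROL", , drop = FALSE],
                        "CONTROL"))
  if (nrow(alg)) {
    grp <- c(grp, list(one_group(alg, "ALLERGIC_ALL")))
    for (sev in c("OAS", "URT_ANG", "ANAPH"))
      if (any(alg$severity == sev))
        grp <- c(grp, list(one_group(alg[alg$severity == sev, ], sev)))
  }
  groups <- do.call(rbind, grp)
  rownames(groups) <- NULL

  ga <- alg[!is.na(alg$peanut_group) & alg$peanut_group == "A_TOLERANT", ]
  gb <- alg[!is.na(alg$peanut_group) & alg$peanut_group == "B_ALLERGIC", ]
  derived <- list(
    oas_share      = percentage(sum(alg$severity == "OAS"), nrow(alg)),
    urt_ang_share  = percentage(sum(alg$severity == "URT_ANG"), nrow(alg)),
    anaph_share    = percentage(sum(alg$severity == "ANAPH"), nrow(alg)),
    group_a_share  = percentage(nrow(ga), nrow(alg)),
    group_b_share  = percentage(nrow(gb), nrow(alg)),
    group_a_spt_peach_pos  = percentage(sum(spt_positive(ga$spt_peach_area)), nrow(ga)),
    group_a_spt_peanut_pos = percentage(sum(spt_positive(ga$spt_peanut_area)), nrow(ga)),
    group_b_spt_peanut_pos = percentage(sum(spt_positive(gb$spt_peanut_area)), nrow(gb))
  )
  structure(list(groups = groups, derived = derived),
            class = "bat_cohort_summary")
}

#' @export
print.bat_cohort_summary <- function(x, ...) {
  print(x$groups)
  cat("\nDerived percentages (numerator/denominator):\n")
  for (nm in names(x$derived)) {
    d <- x$derived[[nm]]
    cat(sprintf("  %-24s %6.2f%%  (%d/%d)\n", nm, d$pct, d$numerator,
                d$denominator))
  }
  invisible(x)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' All pairwise z-tests on mean ranks with the tie-corrected pooled
#' variance, the standard follow-up to a Kruskal-Wallis omnibus test.
#' Raw two-sided p-values are adjusted by the chosen method (Bonferroni by
#' default).
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param p_adjust_method adjustment method for [stats::p.adjust()].
#' @return data frame: `group1`, `group2`, `z`, `p_value`, `adjusted_p`.
#' @export
dunn_test <- function(values, groups, p_adjust_method = "bonferroni") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[[p[1]]] - rbar[[p[2]]]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
  })
  pv <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_value = pv,
             adjusted_p = stats::p.adjust(pv, method = p_adjust_method))
}

#' Compare a variable across groups with the study's statistical plan
#'
#' Dispatches the comparison the analysis plan prescribes: for two
#' independent groups an unpaired t test (parametric) or Mann-Whitney test
#' (nonparametric); for paired data a paired t or Wilcoxon signed-rank
#' test; for more than two groups a one-way ANOVA with Bonferroni-adjusted
#' pairwise t tests, or a Kruskal-Wallis omnibus with Dunn's post hoc
#' test.  With `scale = "auto"` the parametric branch is taken only when
#' every group passes a Shapiro-Wilk normality check at alpha = 0.05 (the
#' dispatch decision is recorded in the result).
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`.  For paired
#'   designs the observations must be ordered identically within each of
#'   the two groups.
#' @param design `"independent"` or `"paired"` (paired requires exactly
#'   two groups of equal size).
#' @param scale `"auto"`, `"parametric"` or `"nonparametric"`.
#' @return list of class `bat_comparison`: `test` (name used), `scale`
#'   (branch taken), `statistic`, `p_value`, and for >2 groups `posthoc`
#'   (pairwise table with `adjusted_p`), plus `direction` (sign of the
#'   first-minus-second group location difference for two groups).
#' @export
compare_groups <- function(values, groups,
                           design = c("independent", "paired"),
                           scale = c("auto", "parametric", "nonparametric")) {
  design <- match.arg(design)
  scale <- match.arg(scale)
  groups <- factor(groups)
  if (nlevels(groups) < 2) input_error("compare_groups: need >= 2 groups")
  ns <- table(groups)
  if (any(ns == 0)) input_error("compare_groups: every group must be nonempty")
  if (any(ns < 2)) input_error("compare_groups: groups of size < 2 cannot ",
                               "support the variance-based tests")
  if (scale == "auto") {
    normal <- all(tapply(values, groups, function(x) {
      if (length(unique(x)) < 3) return(FALSE)
      stats::shapiro.test(x)$p.value >= 0.05
    }))
    scale <- if (normal) "parametric" else "nonparametric"
  }
  lv <- levels(groups)
  res <- list(scale = scale, posthoc = NULL, direction = NA_real_)

  if (design == "paired") {
    if (nlevels(groups) != 2 || ns[1] != ns[2])
      input_error("compare_groups: paired design needs two equal-size groups")
    x <- values[groups == lv[1]]; y <- values[groups == lv[2]]
    t <- if (scale == "parametric") stats::t.test(x, y, paired = TRUE)
         else suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                  exact = FALSE))
    res$test <- if (scale == "parametric") "paired-t" else "Wilcoxon-paired"
    res$statistic <- unname(t$statistic); res$p_value <- t$p.value
    res$direction <- sign(stats::median(x - y))
  } else if (nlevels(groups) == 2) {
    x <- values[groups == lv[1]]; y <- values[groups == lv[2]]
    t <- if (scale == "parametric") stats::t.test(x, y)
         else suppressWarnings(stats::wilcox.test(x, y,
                                                  exact = (length(values) <= 50)))
    res$test <- if (scale == "parametric") "unpaired-t" else "Mann-Whitney"
    res$statistic <- unname(t$statistic); res$p_value <- t$p.value
    res$direction <- sign(stats::median(x) - stats::median(y))
  } else if (scale == "parametric") {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    res$test <- "ANOVA+Bonferroni"
    res$statistic <- an[["F value"]][1]; res$p_value <- an[["Pr(>F)"]][1]
    pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "none",
                                 pool.sd = FALSE)
    pm <- pw$p.value
    rows <- which(!is.na(pm), arr.ind = TRUE)
    raw <- pm[rows]
    res$posthoc <- data.frame(
      group1 = rownames(pm)[rows[, 1]], group2 = colnames(pm)[rows[, 2]],
      p_value = raw,
      adjusted_p = stats::p.adjust(raw, method = "bonferroni"))
  } else {
    kw <- stats::kruskal.test(values, groups)
    res$test <- "Kruskal-Wallis+Dunn"
    res$statistic <- unname(kw$statistic); res$p_value <- kw$p.value
    res$posthoc <- dunn_test(values, groups)
  }
  structure(res, class = "bat_comparison")
}

#' @export
print.bat_comparison <- function(x, ...) {
  cat(x$test, ": statistic =", signif(x$statistic, 4),
      ", p =", signif(x$p_value, 4), "\n")
  if (!is.null(x$posthoc)) { cat("Post hoc:\n"); print(x$posthoc) }
  invisible(x)
}

#' Correlation with missing-pair handling
#'
#' Spearman (default) or Pearson correlation with two-sided p-value;
#' pairs with a missing value in either variable are dropped, and at
#' least three complete pairs are required.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"spearman"` or `"pearson"`.
#' @return list with `r`, `p_value`, `n` (complete pairs), `method`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) input_error("correlate: unequal lengths")
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) input_error("correlate: fewer than 3 complete pairs")
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       method = method)
}
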