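#' Nonresponder rule for a BAT series
#'
#' A subject's basophils are considered responsive to the allergen when the
#' peak activation across concentrations reaches an absolute minimum and
#' clears the unstimulated background by a fold factor.  Nonresponders are
#' excluded from curve-derived quantities such as CD-sens.
#'
#' @param activation_pct percent activation at each concentration.
#' @param background_pct percent activation in the unstimulated well(s).
#' @param min_peak minimum peak activation in percent (default 5).
#' @param fold_over_background required fold over background (default 2).
#' @param background_floor floor applied to the background before the fold
#'   comparison, in percent (default 0.5), so that near-zero backgrounds do
#'   not make the fold criterion vacuous.
#' @return logical scalar.
#' @examples
#' is_responder(c(2, 10, 30), background_pct = 1)   # TRUE
#' is_responder(c(1, 2, 3),  background_pct = 1)    # FALSE (peak < 5)
#' is_responder(c(2, 4, 6),  background_pct = 4)    # FALSE (6 < 2 * 4)
#' @export
is_responder <- function(activation_pct, background_pct,
                         min_peak = 5, fold_over_background = 2,
                         background_floor = 0.5) {
  peak <- max(activation_pct)
  peak >= min_peak &&
    peak >= fold_over_background * max(background_pct, background_floor)
}

#' Fit a four-parameter log-logistic curve to a BAT series
#'
#' Least-squares fit of [latent_logistic()] to percent activation versus
#' log10 concentration, with box constraints (baseline and Emax
#' nonnegative, baseline + Emax <= 100, Hill slope in \[0.3, 5\], log10
#' EC50 within one decade of the measured concentration range) and
#' multistart initialisation: one start per measured concentration for the
#' EC50 times a small slope grid, refined by L-BFGS-B.  This guards
#' against EC50 local minima when most points sit on the plateau.
#'
#' @param activation_pct percent activation, aligned to `concentrations`.
#' @param concentrations increasing positive concentrations in ug/mL;
#'   at least 4 points are required.
#' @param background_pct unstimulated-well percent activation (used for the
#'   responder rule and reported alongside the fit).
#' @param min_peak,fold_over_background passed to [is_responder()].
#' @return a one-row data frame of class `bat_fit`: `baseline_hat`,
#'   `emax_hat`, `log10_ec50_hat`, `slope_hat`, `cd_sens`, `curve_auc`,
#'   `responder`, `fit_converged`.  For nonresponders only `baseline_hat`
#'   (the mean response) and `curve_auc` are defined; the sigmoid
#'   parameters and `cd_sens` are `NA`.
#' @examples
#' conc <- 10^seq(-7, -1)
#' y <- latent_logistic(conc, b = 0, E = 40, m = -4, h = 1)
#' fit_curve(y, conc)
#' @export
fit_curve <- function(activation_pct, concentrations, background_pct = 0,
                      min_peak = 5, fold_over_background = 2) {
  y <- activation_pct
  if (length(y) != length(concentrations))
    input_error("fit_curve: activation and concentration lengths differ")
  if (length(y) < 4)
    input_error("fit_curve: at least 4 concentration points are required")
  if (any(y < 0 | y > 100))
    input_error("fit_curve: percentages must lie in [0, 100]")
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0))
    input_error("fit_curve: concentrations must be positive and increasing")

  lx <- log10(concentrations)
  auc <- curve_auc(y, concentrations, background_pct = background_pct)
  resp <- is_responder(y, background_pct, min_peak, fold_over_background)

  out <- data.frame(baseline_hat = NA_real_, emax_hat = NA_real_,
                    log10_ec50_hat = NA_real_, slope_hat = NA_real_,
                    cd_sens = NA_real_, curve_auc = auc,
                    responder = resp, fit_converged = FALSE)
  class(out) <- c("bat_fit", "data.frame")

  if (diff(range(y)) == 0) {          # flat series: degenerate but valid
    out$baseline_hat <- y[1]; out$emax_hat <- 0; out$fit_converged <- TRUE
    return(out)
  }
  if (!resp) {                        # nonresponder: baseline only
    out$baseline_hat <- mean(y); out$fit_converged <- TRUE
    return(out)
  }

  lower <- c(b = 0, E = 0, m = min(lx) - 1, h = 0.3)
  upper <- c(b = 100, E = 100, m = max(lx) + 1, h = 5)
  sse <- function(p) {
    pen <- max(0, p[1] + p[2] - 100)^2 * 1e6
    sum((y - (p[1] + p[2] / (1 + 10^(p[4] * (p[3] - lx)))))^2) + pen
  }
  b0 <- max(min(y), 0); E0 <- max(max(y) - min(y), 1)
  best <- NULL; best_conv <- NULL
  for (m0 in lx) for (h0 in c(0.7, 1.5, 3)) {
    f <- tryCatch(
      stats::optim(c(b0, E0, m0, h0), sse, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$value < best$value) best <- f
    if (f$convergence == 0 &&
        (is.null(best_conv) || f$value < best_conv$value)) best_conv <- f
  }
  if (is.null(best)) return(out)
  # a cleanly converged start whose loss matches the overall best wins;
  # line-search hiccups at an already-optimal start are not failures
  if (!is.null(best_conv) &&
      best_conv$value <= best$value + 1e-6 * (1 + best$value)) best <- best_conv

  p <- best$par
  out$baseline_hat <- p[1]
  out$emax_hat <- min(p[2], 100 - p[1])
  out$log10_ec50_hat <- p[3]
  out$slope_hat <- p[4]
  out$fit_converged <- best$convergence == 0
  if (out$fit_converged) out$cd_sens <- 100 / 10^p[3]
  out
}

#' CD-sens: basophil allergen threshold sensitivity
#'
#' CD-sens is the inverse of the allergen concentration eliciting half of
#' the maximal activation-marker upregulation, scaled by 100:
#' `100 / EC50` with EC50 in ug/mL.  Higher CD-sens means more sensitive
#' basophils (a response at lower allergen dose).  The half-maximal
#' concentration is taken from the fitted curve (`10^log10_ec50_hat`),
#' which is more stable under counting noise than interpolating between
#' measured points; set `interpolate = TRUE` to use log-linear
#' interpolation of the measured series instead (sensitivity analysis).
#'
#' @param fit a `bat_fit` row from [fit_curve()]; or, with
#'   `interpolate = TRUE`, supply `activation_pct` and `concentrations`.
#' @param interpolate use measured-point interpolation instead of the fit.
#' @param activation_pct,concentrations series used when `interpolate = TRUE`.
#' @return CD-sens (dimensionless given the ug/mL convention).
#' @examples
#' # EC50 of 0.01 ug/mL: CD-sens = 100 / 0.01 = 1e4
#' @export
cd_sens <- function(fit = NULL, interpolate = FALSE,
                    activation_pct = NULL, concentrations = NULL) {
  if (interpolate) {
    y <- activation_pct; lx <- log10(concentrations)
    half <- min(y) + (max(y) - min(y)) / 2
    i <- which(y >= half)[1]
    if (is.na(i)) input_error("cd_sens: no half-maximal crossing")
    l50 <- if (i == 1) lx[1] else
      lx[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (lx[i] - lx[i - 1])
    return(100 / 10^l50)
  }
  if (!isTRUE(fit$responder) || !isTRUE(fit$fit_converged) ||
      is.na(fit$log10_ec50_hat))
    input_error("cd_sens: undefined for nonresponders ",
                "(basophil sensitivity cannot be calculated in nonallergic ",
                "individuals) or unconverged fits")
  100 / 10^fit$log10_ec50_hat
}

#' Area under the activation curve on the log-concentration axis
#'
#' Trapezoidal integral of background-subtracted percent activation
#' (floored at zero) over log10 concentration.  Unlike CD-sens this
#' requires no sigmoid fit and is defined for every subject, including
#' controls; it combines reactivity (curve height) and sensitivity (how
#' early the curve rises) in one number.  Units are percent x log10
#' concentration decades; values are comparable within a run only.
#'
#' @param activation_pct percent activation per concentration.
#' @param concentrations increasing positive concentrations (>= 2 points).
#' @param background_pct scalar background percent subtracted before
#'   integration (default 0); set `subtract_background = FALSE` to
#'   integrate the raw percentages.
#' @param subtract_background,log_axis switches for the integration
#'   convention (defaults: subtract and integrate on log10 axis).
#' @return nonnegative scalar.
#' @examples
#' curve_auc(rep(10, 7), 10^seq(-7, -1))  # 10 over 6 decades = 60
#' @export
curve_auc <- function(activation_pct, concentrations, background_pct = 0,
                      subtract_background = TRUE, log_axis = TRUE) {
  if (length(activation_pct) < 2)
    input_error("curve_auc: at least 2 points are required")
  x <- if (log_axis) log10(concentrations) else concentrations
  y <- if (subtract_background) pmax(activation_pct - background_pct, 0)
       else activation_pct
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Fit every series in a cohort
#'
#' Applies [fit_curve()] to each subject x allergen x marker series in a
#' long-format BAT table.
#'
#' @param bat long-format BAT data frame (`subject_id`, `allergen`,
#'   `marker`, `background_pct`, `concentration`, `activation_pct`).
#' @param min_peak,fold_over_background responder-rule thresholds.
#' @return data frame with one row per series: the key columns plus all
#'   `bat_fit` fields.
#' @export
fit_cohort <- function(bat, min_peak = 5, fold_over_background = 2) {
  key <- interaction(bat$subject_id, bat$allergen, bat$marker, drop = TRUE)
  res <- lapply(split(bat, key), function(d) {
    d <- d[order(d$concentration), ]
    f <- fit_curve(d$activation_pct, d$concentration,
                   background_pct = d$background_pct[1],
                   min_peak = min_peak,
                   fold_over_background = fold_over_background)
    cbind(d[1, c("subject_id", "allergen", "marker")], f,
          row.names = NULL)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select the concentrations that best discriminate allergic from control
#'
#' Ranks each concentration by the two-sample rank statistic (the
#' Mann-Whitney AUC of allergic versus control activation, see
#' [roc_auc()]), breaking ties toward the higher concentration, and
#' returns the top `k` in ascending order.  On cohorts whose activation
#' plateaus at the upper doses this selects the highest concentrations.
#'
#' @param bat long-format BAT table.
#' @param subjects subject metadata with `subject_id` and `cohort`.
#' @param k number of concentrations to select.
#' @param marker activation marker to rank on (default `"CD63"`).
#' @param allergen allergen to rank on (default `"PRU_P_3"`).
#' @return numeric vector of `k` concentrations, ascending.
#' @export
select_discriminating_concentrations <- function(bat, subjects, k,
                                                 marker = "CD63",
                                                 allergen = "PRU_P_3") {
  d <- bat[bat$marker == marker & bat$allergen == allergen, ]
  d$cohort <- subjects$cohort[match(d$subject_id, subjects$subject_id)]
  if (!all(c("CONTROL", "ALLERGIC") %in% d$cohort))
    input_error("select_discriminating_concentrations: both cohorts must ",
                "be represented")
  conc <- sort(unique(d$concentration))
  if (k > length(conc))
    input_error("select_discriminating_concentrations: k exceeds the ",
                "number of concentrations")
  stat <- vapply(conc, function(cc) {
    dd <- d[d$concentration == cc, ]
    roc_auc(dd$activation_pct[dd$cohort == "ALLERGIC"],
            dd$activation_pct[dd$cohort == "CONTROL"])
  }, numeric(1))
  # rank by separation, ties toward the higher concentration
  ord <- order(-stat, -conc)
  sort(conc[ord[seq_len(k)]])
}
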