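#' Four-parameter log-logistic activation curve
#'
#' The latent dose-response model behind every simulated basophil activation
#' series: percent activation at allergen concentration `conc` is
#' `b + E / (1 + 10^(h * (m - log10(conc))))`, i.e. a sigmoid on the log10
#' concentration axis rising from a baseline `b` to a plateau `b + E`, with
#' half-maximal response at `conc = 10^m` (the EC50) and steepness `h`.
#'
#' @param conc allergen concentration(s) in ug/mL; must be > 0.
#' @param b baseline percent activation (unstimulated), in \[0, 100\].
#' @param E maximal allergen-induced increment in percent; `b + E` <= 100.
#' @param m log10 of the EC50 in ug/mL.
#' @param h Hill slope; must be > 0.
#' @return percent activation, same length as `conc`; monotone
#'   nondecreasing in `conc`.
#' @examples
#' latent_logistic(1e-4, b = 0, E = 40, m = -4, h = 1)  # half-max: 20
#' @export
latent_logistic <- function(conc, b, E, m, h) {
  if (any(conc <= 0)) input_error("latent_logistic: 'conc' must be > 0")
  if (b < 0 || E < 0 || b + E > 100)
    input_error("latent_logistic: need 0 <= b and 0 <= E and b + E <= 100")
  if (h <= 0) input_error("latent_logistic: Hill slope 'h' must be > 0")
  b + E / (1 + 10^(h * (m - log10(conc))))
}

## ---- simulation configuration ---------------------------------------------

#' Default per-group parameter blocks for the cohort simulator
#'
#' One block per group (`CONTROL`, `OAS`, `URT_ANG`, `ANAPH`) giving the
#' sampling distributions for the latent dose-response parameters and the
#' clinical covariates.  Dose-response parameters (`emax`, `log10_ec50`,
#' `hill`, `baseline`) are truncated normals / lognormals; IgE and skin
#' prick test (SPT) wheal areas are lognormal, parameterised by the median
#' (`med`) and the log-scale SD (`sdlog`), calibrated so the simulated
#' medians and interquartile ranges match the orders of magnitude reported
#' for LTP-allergic cohorts (e.g. median specific IgE to Pru p 3 of a few
#' kU/L in allergic subjects versus ~0.01 kU/L in controls).  These are
#' documentation-grade defaults, not ground truth.
#'
#' @return named list of group blocks.
#' @export
default_group_blocks <- function() {
  # allergic dose-response block shared by severities: reactivity does not
  # separate severity groups, so only covariate blocks differ
  dr_allergic <- list(
    emax       = c(mean = 45, sd = 15, min = 15, max = 90),
    log10_ec50 = c(mean = -4, sd = 0.8, min = -6.5, max = -1.5),
    hill       = c(meanlog = 0, sdlog = 0.3, min = 0.5, max = 4),
    baseline   = c(mean = 1, sd = 0.3, min = 0.2, max = 3)
  )
  dr_control <- list(
    emax       = c(mean = 0, sd = 1, min = 0, max = 2.5),  # half-normal-ish
    log10_ec50 = c(mean = -4, sd = 0.8, min = -6.5, max = -1.5),
    hill       = c(meanlog = 0, sdlog = 0.3, min = 0.5, max = 4),
    baseline   = c(mean = 1, sd = 0.3, min = 0.2, max = 3)
  )
  list(
    CONTROL = c(dr_control, list(
      age        = c(mean = 34.25, sd = 13.79),
      p_female   = 0.6875,
      tige       = c(med = 88.2, sdlog = 0.93),
      sige_prup3 = c(med = 0.01, sdlog = 2.79, cap = 0.34),
      sige_arah9 = c(med = 0.004, sdlog = 2.5, cap = 0.34),
      spt_peach  = c(max = 6.9),   # uniform below the 7 mm^2 positivity line
      spt_peanut = c(max = 6.9)
    )),
    OAS = c(dr_allergic, list(
      age        = c(mean = 32.30, sd = 9.09),
      p_female   = 0.5652,
      tige       = c(med = 186.5, sdlog = 0.66),
      sige_prup3 = c(med = 4.26, sdlog = 1.11),
      sige_arah9 = c(med = 12.8, sdlog = 2.20),
      spt_peach  = c(med = 36, sdlog = 0.69),
      spt_peanut = c(med = 25, sdlog = 1.33)
    )),
    URT_ANG = c(dr_allergic, list(
      age        = c(mean = 34.75, sd = 11.10),
      p_female   = 0.7273,
      tige       = c(med = 115, sdlog = 1.36),
      sige_prup3 = c(med = 4.82, sdlog = 1.40),
      sige_arah9 = c(med = 1.31, sdlog = 2.0),
      spt_peach  = c(med = 54, sdlog = 0.68),
      spt_peanut = c(med = 30, sdlog = 0.81)
    )),
    ANAPH = c(dr_allergic, list(
      age        = c(mean = 31.22, sd = 9.47),
      p_female   = 0.72,
      tige       = c(med = 121.5, sdlog = 1.75),
      sige_prup3 = c(med = 8.73, sdlog = 1.42),
      sige_arah9 = c(med = 0.74, sdlog = 2.29),
      spt_peach  = c(med = 65, sdlog = 0.81),
      spt_peanut = c(med = 30, sdlog = 0.73)
    ))
  )
}

#' Simulation configuration for a synthetic BAT cohort
#'
#' Builds and validates the configuration driving [simulate_cohort()].  The
#' defaults reproduce the structure of the study cohort the package models:
#' 16 healthy controls and 92 LTP-allergic subjects split 23/44/25 into
#' oral allergy syndrome (OAS), urticaria/angioedema (URT_ANG) and
#' anaphylaxis (ANAPH) severity groups, of whom 37 are additionally
#' peanut-allergic (Group B) and the remaining 55 peanut-tolerant
#' (Group A); seven ten-fold allergen concentrations from 1e-7 to 0.1
#' ug/mL; and severity-dependent profilin co-sensitization probabilities.
#'
#' @param n_controls,n_oas,n_urt_ang,n_anaph group sizes (counts >= 0).
#' @param n_group_b number of peanut-allergic subjects among the allergic;
#'   must not exceed the allergic total.
#' @param concentrations strictly increasing positive allergen
#'   concentrations in ug/mL.
#' @param n_events_per_well basophil events counted per well; observed
#'   percentages are binomial draws of this many trials.  `Inf` (or
#'   `exact_curves = TRUE`) disables counting noise.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param exact_curves if `TRUE`, observed activation equals the latent
#'   curve exactly (noise-free mode).
#' @param profilin_probs named probabilities of profilin sensitization per
#'   severity group (`OAS`, `URT_ANG`, `ANAPH`), each in \[0, 1\].
#' @param group_parameter_blocks per-group sampling distributions; see
#'   [default_group_blocks()].
#' @param arah9_group_a_factor range (length 2) of the multiplicative
#'   attenuation of the Ara h 9 Emax relative to Pru p 3 in peanut-tolerant
#'   Group A subjects; Group B subjects get `arah9_group_b_factor`
#'   (comparable responses).
#' @param arah9_group_b_factor see above.
#' @param attenuate_arah9_cd203c if `FALSE` (default) the Group A Ara h 9
#'   attenuation applies to the CD63 readout only, leaving CD203c
#'   comparable between allergens; set `TRUE` to attenuate both markers.
#' @param reactivity_sensitivity_coupling correlation-inducing loading in
#'   \[0, 1) of a shared per-subject latent sensitization factor on Emax
#'   (positively) and log10 EC50 (negatively): strongly sensitized
#'   subjects react more and at lower doses, the coupling behind the
#'   strong CD-sens / curve-AUC correlations BAT cohorts show.  0 makes
#'   reactivity and sensitivity independent.
#' @param markers activation markers to simulate.
#' @param allergens allergens to simulate.
#' @return an object of class `bat_sim_config`.
#' @export
bat_sim_config <- function(n_controls = 16, n_oas = 23, n_urt_ang = 44,
                           n_anaph = 25, n_group_b = 37,
                           concentrations = 10^seq(-7, -1),
                           n_events_per_well = 500,
                           seed = 1L,
                           exact_curves = FALSE,
                           profilin_probs = c(OAS = 0.3044, URT_ANG = 0.1591,
                                              ANAPH = 0.04),
                           group_parameter_blocks = default_group_blocks(),
                           arah9_group_a_factor = c(0.35, 0.65),
                           arah9_group_b_factor = c(0.85, 1.05),
                           attenuate_arah9_cd203c = FALSE,
                           reactivity_sensitivity_coupling = 0.7,
                           markers = c("CD63", "CD203c"),
                           allergens = c("PRU_P_3", "ARA_H_9")) {
  cfg <- list(
    n_controls = n_controls, n_oas = n_oas, n_urt_ang = n_urt_ang,
    n_anaph = n_anaph, n_group_b = n_group_b,
    concentrations = concentrations,
    n_events_per_well = n_events_per_well, seed = seed,
    exact_curves = exact_curves, profilin_probs = profilin_probs,
    group_parameter_blocks = group_parameter_blocks,
    arah9_group_a_factor = arah9_group_a_factor,
    arah9_group_b_factor = arah9_group_b_factor,
    attenuate_arah9_cd203c = attenuate_arah9_cd203c,
    reactivity_sensitivity_coupling = reactivity_sensitivity_coupling,
    markers = markers, allergens = allergens
  )
  validate_sim_config(cfg)
  structure(cfg, class = "bat_sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_controls", "n_oas", "n_urt_ang", "n_anaph", "n_group_b")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      input_error("invalid configuration: '", f,
                  "' must be a single nonnegative integer")
  }
  n_allergic <- cfg$n_oas + cfg$n_urt_ang + cfg$n_anaph
  if (cfg$n_group_b > n_allergic)
    input_error("invalid configuration: 'n_group_b' exceeds the number of ",
                "allergic subjects")
  cc <- cfg$concentrations
  if (length(cc) < 1 || any(cc <= 0) || any(diff(cc) <= 0))
    input_error("invalid configuration: 'concentrations' must be strictly ",
                "increasing and positive")
  if (!(is.infinite(cfg$n_events_per_well) ||
        (cfg$n_events_per_well >= 1 &&
         cfg$n_events_per_well == round(cfg$n_events_per_well))))
    input_error("invalid configuration: 'n_events_per_well' must be a ",
                "positive integer or Inf")
  if (any(cfg$profilin_probs < 0) || any(cfg$profilin_probs > 1))
    input_error("invalid configuration: 'profilin_probs' must lie in [0, 1]")
  if (!all(c("OAS", "URT_ANG", "ANAPH") %in% names(cfg$profilin_probs)))
    input_error("invalid configuration: 'profilin_probs' must name ",
                "OAS, URT_ANG and ANAPH")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    input_error("invalid configuration: 'seed' must be a single integer")
  lam <- cfg$reactivity_sensitivity_coupling
  if (!is.numeric(lam) || length(lam) != 1 || is.na(lam) || lam < 0 || lam >= 1)
    input_error("invalid configuration: 'reactivity_sensitivity_coupling' ",
                "must lie in [0, 1)")
  invisible(cfg)
}

## ---- sampling helpers ------------------------------------------------------

rnorm_trunc <- function(n, p) {
  pmin(pmax(stats::rnorm(n, p[["mean"]], p[["sd"]]), p[["min"]]), p[["max"]])
}

rlnorm_med <- function(n, p) {
  x <- stats::rlnorm(n, meanlog = log(p[["med"]]), sdlog = p[["sdlog"]])
  if ("cap" %in% names(p)) x <- pmin(x, p[["cap"]])
  x
}

rhill <- function(n, p) {
  pmin(pmax(stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
            p[["min"]]), p[["max"]])
}

## ---- cohort simulation -----------------------------------------------------

#' Simulate a synthetic BAT cohort
#'
#' Generates subject metadata and per-well basophil activation series with
#' the statistical structure the downstream analysis assumes.  Allergic
#' subjects carry a latent four-parameter log-logistic activation curve per
#' allergen and marker (see [latent_logistic()]); controls carry near-flat
#' curves at background scale.  The observed percent activation in each
#' well is a binomial draw of `n_events_per_well` basophil events with
#' success probability equal to the latent curve value / 100 — the minimal
#' counting-noise mechanism consistent with flow-cytometry summary
#' percentages.  Peanut-allergic Group B subjects receive an Ara h 9
#' response comparable to their Pru p 3 response; peanut-tolerant Group A
#' subjects a strictly attenuated one (CD63 readout only by default).
#'
#' @param config a [bat_sim_config()] object.
#' @return a list of class `bat_cohort` with components
#'   \describe{
#'     \item{subjects}{data frame, one row per subject: `subject_id`,
#'       `cohort` (CONTROL/ALLERGIC), `severity` (NONE/OAS/URT_ANG/ANAPH),
#'       `peanut_group` (NA/A_TOLERANT/B_ALLERGIC), `profilin_sensitized`,
#'       `age`, `sex`, `total_ige`, `sige_prup3`, `sige_arah9`,
#'       `spt_peach_area`, `spt_peanut_area`.}
#'     \item{bat}{long-format data frame, one row per well: `subject_id`,
#'       `allergen`, `marker`, `background_pct`, `concentration`,
#'       `activation_pct`.}
#'     \item{truth}{latent curve parameters per subject x allergen x
#'       marker, for parameter-recovery studies.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' coh <- simulate_cohort(bat_sim_config(seed = 42))
#' nrow(coh$subjects)  # 108
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "bat_sim_config")) config <- do.call(bat_sim_config, config)
  validate_sim_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(config$seed))

  sev_counts <- c(NONE = config$n_controls, OAS = config$n_oas,
                  URT_ANG = config$n_urt_ang, ANAPH = config$n_anaph)
  severity <- rep(names(sev_counts), sev_counts)
  n <- length(severity)
  cohort <- ifelse(severity == "NONE", "CONTROL", "ALLERGIC")
  subject_id <- sprintf("S%03d", seq_len(n))
  blocks <- config$group_parameter_blocks
  blk_name <- ifelse(severity == "NONE", "CONTROL", severity)

  # peanut groups: sample Group B uniformly among the allergic subjects
  peanut_group <- rep(NA_character_, n)
  idx_all <- which(cohort == "ALLERGIC")
  idx_b <- if (config$n_group_b > 0) sample(idx_all, config$n_group_b) else integer(0)
  peanut_group[idx_all] <- "A_TOLERANT"
  peanut_group[idx_b] <- "B_ALLERGIC"

  profilin <- rep(FALSE, n)
  for (sev in c("OAS", "URT_ANG", "ANAPH")) {
    i <- which(severity == sev)
    if (length(i))
      profilin[i] <- stats::runif(length(i)) < config$profilin_probs[[sev]]
  }

  draw_cov <- function(i) {
    b <- blocks[[blk_name[i]]]
    spt <- function(p) {
      if ("med" %in% names(p)) max(rlnorm_med(1, p), 7)  # allergic: SPT positive
      else stats::runif(1, 0, p[["max"]])                # control: below threshold
    }
    c(age = max(18, stats::rnorm(1, b$age[["mean"]], b$age[["sd"]])),
      female = as.numeric(stats::runif(1) < b$p_female),
      total_ige = rlnorm_med(1, b$tige),
      sige_prup3 = rlnorm_med(1, b$sige_prup3),
      sige_arah9 = rlnorm_med(1, b$sige_arah9),
      spt_peach_area = spt(b$spt_peach),
      spt_peanut_area = spt(b$spt_peanut))
  }
  cov <- t(vapply(seq_len(n), draw_cov, numeric(7)))

  subjects <- data.frame(
    subject_id = subject_id,
    cohort = cohort,
    severity = severity,
    peanut_group = peanut_group,
    profilin_sensitized = profilin,
    age = cov[, "age"],
    sex = ifelse(cov[, "female"] == 1, "F", "M"),
    total_ige = cov[, "total_ige"],
    sige_prup3 = cov[, "sige_prup3"],
    sige_arah9 = cov[, "sige_arah9"],
    spt_peach_area = cov[, "spt_peach_area"],
    spt_peanut_area = cov[, "spt_peanut_area"],
    stringsAsFactors = FALSE
  )

  conc <- config$concentrations
  n_conc <- length(conc)
  noise_free <- isTRUE(config$exact_curves) || is.infinite(config$n_events_per_well)
  observe <- function(latent_pct) {
    if (noise_free) return(latent_pct)
    N <- config$n_events_per_well
    100 * stats::rbinom(length(latent_pct), N, pmin(pmax(latent_pct, 0), 100) / 100) / N
  }

  truth <- list(); bat <- list(); k <- 0L
  lam <- config$reactivity_sensitivity_coupling
  res_load <- sqrt(1 - lam^2)
  for (i in seq_len(n)) {
    b <- blocks[[blk_name[i]]]
    u_i <- stats::rnorm(1)   # latent sensitization strength of this subject
    for (marker in config$markers) {
      # marker-specific Pru p 3 curve; the shared factor pushes Emax up and
      # the EC50 down together in strongly sensitized subjects
      z_e <- lam * u_i + res_load * stats::rnorm(1)
      z_m <- lam * u_i + res_load * stats::rnorm(1)
      emax_pp3 <- pmin(pmax(b$emax[["mean"]] + b$emax[["sd"]] * z_e,
                            b$emax[["min"]]), b$emax[["max"]])
      m_pp3 <- pmin(pmax(b$log10_ec50[["mean"]] - b$log10_ec50[["sd"]] * z_m,
                         b$log10_ec50[["min"]]), b$log10_ec50[["max"]])
      hill <- rhill(1, b$hill)
      base <- rnorm_trunc(1, b$baseline)
      for (allergen in config$allergens) {
        if (allergen == "PRU_P_3" || cohort[i] == "CONTROL") {
          emax <- if (allergen == "PRU_P_3") emax_pp3 else rnorm_trunc(1, b$emax)
          m <- if (allergen == "PRU_P_3") m_pp3 else rnorm_trunc(1, b$log10_ec50)
        } else {
          fac_range <- if (peanut_group[i] == "B_ALLERGIC") {
            config$arah9_group_b_factor
          } else if (marker == "CD63" || isTRUE(config$attenuate_arah9_cd203c)) {
            config$arah9_group_a_factor
          } else {
            config$arah9_group_b_factor
          }
          emax <- emax_pp3 * stats::runif(1, fac_range[1], fac_range[2])
          m <- m_pp3 + stats::rnorm(1, 0, 0.3)
        }
        emax <- min(emax, 100 - base)
        m <- pmin(pmax(m, b$log10_ec50[["min"]]), b$log10_ec50[["max"]])
        latent <- latent_logistic(conc, base, emax, m, hill)
        k <- k + 1L
        truth[[k]] <- data.frame(
          subject_id = subject_id[i], allergen = allergen, marker = marker,
          baseline = base, emax = emax, log10_ec50 = m, hill = hill,
          stringsAsFactors = FALSE)
        bat[[k]] <- data.frame(
          subject_id = subject_id[i], allergen = allergen, marker = marker,
          background_pct = observe(base),
          concentration = conc,
          activation_pct = observe(latent),
          stringsAsFactors = FALSE)
      }
    }
  }

  structure(list(subjects = subjects,
                 bat = do.call(rbind, bat),
                 truth = do.call(rbind, truth),
                 config = config),
            class = "bat_cohort")
}

#' @export
print.bat_cohort <- function(x, ...) {
  cat("Synthetic BAT cohort:", nrow(x$subjects), "subjects (",
      sum(x$subjects$cohort == "ALLERGIC"), "allergic /",
      sum(x$subjects$cohort == "CONTROL"), "control ),",
      nrow(x$bat), "wells\n")
  invisible(x)
}
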