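# Shared fixtures, all built in code.

default_concs <- 10^seq(-7, -1)

# one simulated default cohort reused across tests (cheap: metadata + wells)
fixture_cohort <- function(seed = 11, ...) {
  simulate_cohort(bat_sim_config(seed = seed, ...))
}

# a subject table with the published flow-chart counts: 16 controls,
# 92 allergic (23 OAS / 44 URT_ANG / 25 ANAPH), 55 peanut-tolerant Group A
# (54 SPT-peach positive, 6 SPT-peanut positive) and 37 peanut-allergic
# Group B (31 SPT-peanut positive).  Covariates are filler; only counts
# and SPT positivity matter.
printed_cohort <- function() {
  n <- 16 + 92
  severity <- c(rep("NONE", 16), rep("OAS", 23), rep("URT_ANG", 44),
                rep("ANAPH", 25))
  cohort <- ifelse(severity == "NONE", "CONTROL", "ALLERGIC")
  peanut_group <- rep(NA_character_, n)
  idx_allergic <- which(cohort == "ALLERGIC")
  peanut_group[idx_allergic[1:55]] <- "A_TOLERANT"
  peanut_group[idx_allergic[56:92]] <- "B_ALLERGIC"
  spt_peach <- ifelse(cohort == "CONTROL", 2, 50)
  spt_peach[idx_allergic[55]] <- 3            # 54/55 of Group A SPT-peach+
  spt_peanut <- rep(2, n)
  spt_peanut[idx_allergic[1:6]] <- 40         # 6/55 of Group A SPT-peanut+
  spt_peanut[idx_allergic[56:86]] <- 40       # 31/37 of Group B SPT-peanut+
  data.frame(
    subject_id = sprintf("P%03d", seq_len(n)),
    cohort = cohort, severity = severity, peanut_group = peanut_group,
    profilin_sensitized = FALSE, age = 33, sex = "F",
    total_ige = 100, sige_prup3 = ifelse(cohort == "CONTROL", 0.01, 6),
    sige_arah9 = 1, spt_peach_area = spt_peach,
    spt_peanut_area = spt_peanut, stringsAsFactors = FALSE)
}

# brute-force Mann-Whitney AUC by pairwise comparison with half ties
pairwise_auc <- function(a, ctrl) {
  mean(outer(a, ctrl, function(x, y) (x > y) + 0.5 * (x == y)))
}

# exhaustive optimal-cutoff scan over every candidate threshold
bruteforce_cutoff <- function(a, ctrl) {
  pooled <- sort(unique(c(a, ctrl)))
  thr <- c(pooled[1] - 1,
           if (length(pooled) > 1) (head(pooled, -1) + tail(pooled, -1)) / 2,
           pooled[length(pooled)] + 1)
  best <- NULL
  for (t in thr) {
    sens <- 100 * mean(a > t); spec <- 100 * mean(ctrl <= t)
    j <- sens + spec - 100
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) < 1e-12 && (spec > best$spec + 1e-12 ||
          (abs(spec - best$spec) < 1e-12 && t > best$t))))
      best <- list(t = t, j = j, sens = sens, spec = spec)
  }
  best
}
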