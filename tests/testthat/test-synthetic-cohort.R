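test_that("latent logistic curve has the closed-form values and monotonicity", {
  # half-max at the EC50, plateau at b + E
  expect_equal(latent_logistic(1e-4, b = 2, E = 40, m = -4, h = 1), 2 + 20)
  expect_equal(latent_logistic(1e6, b = 2, E = 40, m = -4, h = 1), 42,
               tolerance = 1e-6)
  # direct evaluation one decade below the EC50
  expect_equal(latent_logistic(1e-3, b = 0, E = 40, m = -4, h = 1), 40 / 1.1)
  # monotone nondecreasing in concentration
  y <- latent_logistic(default_concs, b = 1, E = 50, m = -3.5, h = 1.7)
  expect_true(all(diff(y) >= 0))
  expect_error(latent_logistic(0, 0, 40, -4, 1), "conc")
  expect_error(latent_logistic(1e-3, 60, 60, -4, 1), "<= 100")
  expect_error(latent_logistic(1e-3, 0, 40, -4, -1), "slope")
})

test_that("default configuration reproduces the study cohort structure", {
  coh <- fixture_cohort()
  expect_equal(nrow(coh$subjects), 108)
  expect_equal(sum(coh$subjects$cohort == "ALLERGIC"), 92)
  expect_equal(as.integer(table(coh$subjects$severity)[c("OAS", "URT_ANG",
                                                         "ANAPH")]),
               c(23L, 44L, 25L))
  expect_equal(sum(coh$subjects$peanut_group == "B_ALLERGIC", na.rm = TRUE), 37)
  # one series per subject x allergen x marker, aligned to 7 concentrations
  expect_equal(nrow(coh$bat), 108 * 2 * 2 * 7)
  expect_true(all(coh$bat$activation_pct >= 0 & coh$bat$activation_pct <= 100))
  # controls: no profilin, SPT below the positivity threshold, sIgE < 0.35
  ctrl <- coh$subjects[coh$subjects$cohort == "CONTROL", ]
  expect_false(any(ctrl$profilin_sensitized))
  expect_true(all(ctrl$spt_peach_area < 7 & ctrl$spt_peanut_area < 7))
  expect_true(all(ctrl$sige_prup3 < 0.35))
  expect_true(all(is.na(ctrl$peanut_group)))
})

test_that("same config and seed give bit-identical cohorts", {
  a <- fixture_cohort(seed = 5)
  b <- fixture_cohort(seed = 5)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$bat, b$bat)
  c <- fixture_cohort(seed = 6)
  expect_false(identical(a$bat, c$bat))
})

test_that("noise-free mode reproduces the latent curve exactly", {
  coh <- fixture_cohort(seed = 3, exact_curves = TRUE)
  tr <- coh$truth
  key <- paste(coh$bat$subject_id, coh$bat$allergen, coh$bat$marker)
  tkey <- paste(tr$subject_id, tr$allergen, tr$marker)
  j <- match(key, tkey)
  expected <- mapply(function(cc, i)
    latent_logistic(cc, tr$baseline[i], tr$emax[i], tr$log10_ec50[i],
                    tr$hill[i]),
    coh$bat$concentration, j)
  expect_equal(max(abs(coh$bat$activation_pct - expected)), 0)
})

test_that("median allergic Emax-scale activation exceeds controls", {
  coh <- fixture_cohort(seed = 9)
  top <- coh$bat[coh$bat$concentration == 0.1 & coh$bat$marker == "CD63" &
                   coh$bat$allergen == "PRU_P_3", ]
  grp <- coh$subjects$cohort[match(top$subject_id, coh$subjects$subject_id)]
  expect_gt(median(top$activation_pct[grp == "ALLERGIC"]),
            median(top$activation_pct[grp == "CONTROL"]))
})

test_that("binomial counting noise has the flow-cytometry standard deviation", {
  # many wells at a common latent value: sd of observed percent must match
  # 100 * sqrt(p (1 - p) / N) within Monte Carlo error
  N <- 500
  coh <- simulate_cohort(bat_sim_config(
    seed = 21, n_controls = 0, n_oas = 1500, n_urt_ang = 0, n_anaph = 0,
    n_group_b = 0, n_events_per_well = N,
    markers = "CD63", allergens = "PRU_P_3"))
  tr <- coh$truth
  d <- coh$bat[coh$bat$concentration == 0.1, ]
  j <- match(d$subject_id, tr$subject_id)
  latent <- mapply(function(i) latent_logistic(0.1, tr$baseline[i], tr$emax[i],
                                               tr$log10_ec50[i], tr$hill[i]), j)
  p <- latent / 100
  z <- (d$activation_pct - latent) / (100 * sqrt(p * (1 - p) / N))
  expect_equal(sd(z), 1, tolerance = 0.06)
  expect_equal(mean(z), 0, tolerance = 0.06)
})

test_that("group B keeps Ara h 9 reactivity while group A is attenuated", {
  coh <- fixture_cohort(seed = 13, exact_curves = TRUE)
  tr <- coh$truth[coh$truth$marker == "CD63", ]
  wide <- reshape(tr[, c("subject_id", "allergen", "emax")],
                  idvar = "subject_id", timevar = "allergen",
                  direction = "wide")
  grp <- coh$subjects$peanut_group[match(wide$subject_id,
                                         coh$subjects$subject_id)]
  ratio <- wide$emax.ARA_H_9 / wide$emax.PRU_P_3
  expect_true(all(ratio[!is.na(grp) & grp == "A_TOLERANT"] < 0.7))
  expect_gt(median(ratio[!is.na(grp) & grp == "B_ALLERGIC"]), 0.8)
  # by default the CD203c readout is not attenuated in group A
  tr2 <- coh$truth[coh$truth$marker == "CD203c", ]
  wide2 <- reshape(tr2[, c("subject_id", "allergen", "emax")],
                   idvar = "subject_id", timevar = "allergen",
                   direction = "wide")
  grp2 <- coh$subjects$peanut_group[match(wide2$subject_id,
                                          coh$subjects$subject_id)]
  r2 <- wide2$emax.ARA_H_9 / wide2$emax.PRU_P_3
  expect_gt(median(r2[!is.na(grp2) & grp2 == "A_TOLERANT"]), 0.8)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(bat_sim_config(n_controls = -1), "n_controls")
  expect_error(bat_sim_config(n_group_b = 93), "n_group_b")
  expect_error(bat_sim_config(concentrations = c(1e-3, 1e-4)), "concentrations")
  expect_error(bat_sim_config(concentrations = c(-1, 1)), "concentrations")
  expect_error(bat_sim_config(profilin_probs = c(OAS = 1.2, URT_ANG = 0.1,
                                                 ANAPH = 0)), "profilin_probs")
  expect_error(bat_sim_config(n_events_per_well = 0.5), "n_events_per_well")
})
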