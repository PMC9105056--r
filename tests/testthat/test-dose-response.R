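test_that("noise-free log-logistic data are recovered to 1e-3 across the box", {
  set.seed(42)
  for (i in 1:15) {
    b <- runif(1, 0, 3); E <- runif(1, 15, 80)
    m <- runif(1, -6, -2); h <- runif(1, 0.5, 3)
    y <- latent_logistic(default_concs, b, E, m, h)
    f <- fit_curve(y, default_concs, background_pct = b)
    expect_true(f$fit_converged)
    expect_equal(f$baseline_hat, b, tolerance = 1e-3)
    expect_equal(f$emax_hat, E, tolerance = 1e-3)
    expect_equal(f$log10_ec50_hat, m, tolerance = 1e-3)
    expect_equal(f$slope_hat, h, tolerance = 1e-3)
  }
})

test_that("degenerate and insufficient inputs are handled", {
  flat <- rep(1, 7)
  f <- fit_curve(flat, default_concs, background_pct = 1)
  expect_equal(f$emax_hat, 0)
  expect_false(f$responder)
  expect_true(f$fit_converged)
  expect_true(is.na(f$cd_sens))
  expect_error(fit_curve(c(1, 2, 3), 10^(-3:-1)), "4 concentration")
  expect_error(fit_curve(c(1, 2, 3, 101), 10^(-4:-1)), "0, 100")
})

test_that("nonresponder rule combines absolute peak and fold over background", {
  expect_true(is_responder(c(2, 10, 30), background_pct = 1))
  expect_false(is_responder(c(1, 2, 3), background_pct = 1))     # peak < 5
  expect_false(is_responder(c(2, 4, 6), background_pct = 4))     # 6 < 2 * 4
  expect_true(is_responder(c(2, 4, 8.1), background_pct = 4))
  # background floor keeps the fold criterion meaningful at zero background
  expect_false(is_responder(c(0.9, 0.9, 0.9), background_pct = 0,
                            min_peak = 0.5))
})

test_that("nonresponders get baseline only and CD-sens errors", {
  y <- c(1, 1.2, 0.8, 1.1, 1, 0.9, 1.2)
  f <- fit_curve(y, default_concs, background_pct = 1)
  expect_false(f$responder)
  expect_false(is.na(f$baseline_hat))
  expect_true(is.na(f$log10_ec50_hat))
  expect_error(cd_sens(f), "nonresponders|nonallergic")
})

test_that("CD-sens is 100 over the fitted EC50 and antitone in it", {
  f <- data.frame(responder = TRUE, fit_converged = TRUE, log10_ec50_hat = -2)
  expect_equal(cd_sens(f), 1e4)
  f$log10_ec50_hat <- 0
  expect_equal(cd_sens(f), 100)
  # halving the EC50 doubles CD-sens, exactly
  f1 <- f; f1$log10_ec50_hat <- log10(0.02)
  f2 <- f; f2$log10_ec50_hat <- log10(0.01)
  expect_equal(cd_sens(f2) / cd_sens(f1), 2)
  # via exact-data fit: EC50 1e-4 -> CD-sens 1e6 within 0.5%
  y <- latent_logistic(default_concs, 0, 40, -4, 1)
  ff <- fit_curve(y, default_concs)
  expect_equal(cd_sens(ff), 1e6, tolerance = 5e-3)
})

test_that("curve AUC matches the independent trapezoid oracle", {
  skip_if_not_installed("pracma")
  # rectangle: constant 10% over 6 decades
  expect_equal(curve_auc(rep(10, 7), default_concs), 60)
  # activation equal to background everywhere integrates to zero
  expect_equal(curve_auc(rep(3, 7), default_concs, background_pct = 3), 0)
  # piecewise-linear toy, unit log10 spacing
  y <- c(0, 0, 0, 10, 20, 20, 20)
  expect_equal(curve_auc(y, default_concs),
               pracma::trapz(log10(default_concs), y))
  # random vectors against pracma::trapz, with background flooring
  set.seed(1)
  for (i in 1:50) {
    y <- runif(7, 0, 60); bg <- runif(1, 0, 5)
    expect_equal(curve_auc(y, default_concs, background_pct = bg),
                 pracma::trapz(log10(default_concs), pmax(y - bg, 0)),
                 tolerance = 1e-12)
  }
  # appending an endpoint concentration with zero net activation, next to an
  # endpoint already at zero, changes nothing
  y <- c(0, 0, 0, 20, 30, 30, 30)
  a1 <- curve_auc(y[3:7], default_concs[3:7])
  a2 <- curve_auc(y[2:7], default_concs[2:7])
  expect_equal(a1, a2)
})

test_that("EC50 is recovered under binomial counting noise", {
  # 25 subjects, truth m = -4, N = 500 events: mean |error| below 0.3 decades
  set.seed(77)
  errs <- replicate(25, {
    lat <- latent_logistic(default_concs, 1, 45, -4, 1.2)
    y <- 100 * rbinom(7, 500, lat / 100) / 500
    f <- fit_curve(y, default_concs, background_pct = 1)
    abs(f$log10_ec50_hat - (-4))
  })
  expect_lt(mean(errs), 0.3)
})

test_that("interpolated CD-sens tracks the fitted one on clean sigmoids", {
  y <- latent_logistic(default_concs, 0, 40, -3.5, 1)
  ci <- cd_sens(interpolate = TRUE, activation_pct = y,
                concentrations = default_concs)
  expect_equal(log10(ci), log10(100 / 10^-3.5), tolerance = 0.2)
})

test_that("discriminating concentrations are ranked by cohort separation", {
  coh <- fixture_cohort(seed = 15)
  sel <- select_discriminating_concentrations(coh$bat, coh$subjects, k = 3)
  expect_equal(sel, c(1e-3, 1e-2, 1e-1))
  expect_equal(select_discriminating_concentrations(coh$bat, coh$subjects,
                                                    k = 7),
               default_concs)
  # constructed fixture where only one concentration separates the cohorts
  conc <- 10^(-3:-1)
  mk <- function(id, y) data.frame(
    subject_id = id, allergen = "PRU_P_3", marker = "CD63",
    background_pct = 1, concentration = conc, activation_pct = y)
  bat <- rbind(mk("a1", c(5, 40, 5)), mk("a2", c(6, 45, 6)),
               mk("a3", c(5, 42, 5)),
               mk("c1", c(5, 5, 5)), mk("c2", c(6, 6, 6)),
               mk("c3", c(5, 5, 6)))
  subj <- data.frame(subject_id = c("a1", "a2", "a3", "c1", "c2", "c3"),
                     cohort = rep(c("ALLERGIC", "CONTROL"), each = 3))
  expect_equal(select_discriminating_concentrations(bat, subj, k = 1), 1e-2)
  subj$cohort <- "ALLERGIC"
  expect_error(select_discriminating_concentrations(bat, subj, k = 1),
               "both cohorts")
})

test_that("fitting a cohort returns one row per series with responder logic", {
  coh <- fixture_cohort(seed = 4, markers = "CD63", allergens = "PRU_P_3")
  fits <- fit_cohort(coh$bat)
  expect_equal(nrow(fits), 108)
  grp <- coh$subjects$cohort[match(fits$subject_id, coh$subjects$subject_id)]
  # controls are (almost) all nonresponders with undefined CD-sens
  expect_gt(mean(!fits$responder[grp == "CONTROL"]), 0.9)
  expect_true(all(is.na(fits$cd_sens[!fits$responder])))
  # responders carry positive CD-sens and nonnegative curve AUC
  ok <- fits$responder & fits$fit_converged
  expect_true(all(fits$cd_sens[ok] > 0))
  expect_true(all(fits$curve_auc >= 0))
  expect_true(all(fits$baseline_hat[ok] + fits$emax_hat[ok] <= 100 + 1e-9))
})
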