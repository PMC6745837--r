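test_that("the outcome model recovers known covariate effects", {
  sim <- generate_cohort(generator_config(seed = 31))
  m <- suppressWarnings(fit_outcome_model(sim$cohort))
  est <- tidy(m)
  # steep age gradient: 80+ coefficient near its generating value of -3
  age80 <- est[est$term == "age_group80+", ]
  expect_lt(abs(age80$estimate - (-3)), 3.5 * age80$std.error)
  # null covariates stay near zero
  sexM <- est[est$term == "sexM", ]
  expect_lt(abs(sexM$estimate), 3.5 * sexM$std.error)
  expect_true(glance(m)$converged)
})

test_that("degenerate designs raise informative errors", {
  # a level that perfectly predicts treatment
  pts <- make_patients(rep("H1", 40), c(rep(1, 20), rep(0, 20)),
                       grade = rep(c("poor", "well-moderate"), each = 20))
  coh <- cohort(pts, make_hospitals("H1"))
  expect_error(fit_outcome_model(coh, covariates = "grade"),
               class = "act_separation_error", regexp = "grade")

  # all patients treated: no events to contrast
  all1 <- make_count_cohort(n = c(10, 10), k = c(10, 10))
  expect_error(fit_outcome_model(all1, covariates = "sex"),
               "event")
})

test_that("indirect standardization reduces to identity for an intercept-only model", {
  coh <- make_count_cohort(n = c(25, 40, 15), k = c(20, 22, 6))
  m <- fit_outcome_model(coh, covariates = character(0))
  adj <- adjusted_hospital_rates(coh, m, bootstrap_reps = 200, seed = 1)
  pool <- mean(coh$patients$treated)
  expect_equal(adj$expected, rep(pool, 3), tolerance = 1e-9)
  expect_equal(adj$adjusted, adj$observed, tolerance = 1e-9)
  # the adjusted rate is always (observed / expected) x pooled
  expect_equal(adj$adjusted, adj$observed / adj$expected * pool,
               tolerance = 1e-12)
})

test_that("with no real covariate effects, adjusted rates track observed rates", {
  sim <- generate_cohort(generator_config(n_hospitals = 20, n_patients = 1200,
                                          covariate_log_odds = list(),
                                          seed = 32))
  m <- suppressWarnings(fit_outcome_model(sim$cohort))
  adj <- adjusted_hospital_rates(sim$cohort, m, bootstrap_reps = 400, seed = 2)
  draws <- attr(adj, "draws")
  boot_se <- apply(draws, 2, sd)
  expect_true(all(abs(adj$adjusted - adj$observed) <= 3 * boot_se + 1e-6))
  expect_true(all(adj$ci_low <= adj$adjusted & adj$adjusted <= adj$ci_high))
})

test_that("adjustment shrinks hospital deviations when case mix drives them", {
  sim <- generate_cohort(generator_config(
    case_mix_skew_covariate = "age_group", case_mix_skew_sd = 0.6, seed = 33))
  m <- suppressWarnings(fit_outcome_model(sim$cohort))
  adj <- adjusted_hospital_rates(sim$cohort, m, bootstrap_reps = 0)
  pool <- mean(m$data$treated)
  mad_obs <- mean(abs(adj$observed - pool))
  mad_adj <- mean(abs(adj$adjusted - pool))
  expect_lt(mad_adj, mad_obs)
})

test_that("factor effects: hand-computed RR, null RR, and exact collapse without covariates", {
  # 2x2: (k1=30, n1=50) vs (k0=40, n0=100) -> RR 1.5
  coh <- make_count_cohort(n = c(50, 100), k = c(30, 40))
  coh$hospitals$teaching <- c(1L, 0L)
  fe <- factor_effect(coh, "teaching", covariates = character(0),
                      boot_reps = 200, seed = 1)
  expect_equal(fe$rr_unadjusted, 1.5, tolerance = 1e-9)
  # no covariates: marginal standardization collapses to the raw rates
  expect_equal(fe$rr_adjusted, fe$rr_unadjusted, tolerance = 1e-9)
  expect_equal(fe$levels$adj_rate, fe$levels$rate, tolerance = 1e-9)
  expect_true(fe$rr_unadjusted_ci[1] <= 1.5 & 1.5 <= fe$rr_unadjusted_ci[2])

  # identical rates in both levels -> RR exactly 1
  coh2 <- make_count_cohort(n = c(40, 40), k = c(24, 24))
  coh2$hospitals$teaching <- c(1L, 0L)
  fe2 <- factor_effect(coh2, "teaching", covariates = character(0),
                       boot_reps = 0)
  expect_equal(fe2$rr_unadjusted, 1)
  expect_equal(fe2$rr_adjusted, 1, tolerance = 1e-9)

  # constant factor is degenerate
  coh3 <- make_count_cohort(n = c(40, 40), k = c(24, 20))
  expect_error(factor_effect(coh3, "teaching", covariates = character(0)),
               "constant")
})

test_that("the latent-scale ICC is near zero under the null and recovers 0.5", {
  sim0 <- generate_cohort(generator_config(n_hospitals = 40, n_patients = 2000,
                                           covariate_log_odds = list(),
                                           hospital_sd = 0, seed = 34))
  icc0 <- multilevel_icc(sim0$cohort, covariates = character(0))
  expect_lt(icc0$icc, 0.02)

  # hospital variance equal to the logistic residual pi^2/3 gives ICC 1/2
  simh <- generate_cohort(generator_config(
    n_hospitals = 100, n_patients = 20000,
    hospital_size_profile = "uniform", covariate_log_odds = list(),
    hospital_sd = sqrt(pi^2 / 3), seed = 35))
  icch <- multilevel_icc(simh$cohort, covariates = character(0))
  expect_lt(abs(icch$icc - 0.5), 0.08)
  expect_true(icch$icc >= 0 && icch$icc < 1)
})

test_that("ICC and the CV nonrandom component agree in sign", {
  null_sim <- generate_cohort(generator_config(n_hospitals = 50,
                                               n_patients = 4000,
                                               covariate_log_odds = list(),
                                               hospital_sd = 0, seed = 36))
  strong_sim <- generate_cohort(generator_config(n_hospitals = 50,
                                                 n_patients = 4000,
                                                 covariate_log_odds = list(),
                                                 hospital_sd = 1, seed = 36))
  d0 <- decompose_variation(null_sim$cohort, iterations = 300, seed = 1)
  d1 <- decompose_variation(strong_sim$cohort, iterations = 300, seed = 1)
  i0 <- multilevel_icc(null_sim$cohort, covariates = character(0))
  i1 <- multilevel_icc(strong_sim$cohort, covariates = character(0))
  expect_lt(i0$icc, 0.02)
  expect_lt(abs(d0$nonrandom_component), 0.05)
  expect_gt(i1$icc, 0.1)
  expect_gt(d1$nonrandom_component, 0.1)
})

test_that("SES handling: unknown rows drop with a warning or stay as a category", {
  pts <- make_patients(rep("H1", 60), rep(c(1, 0), 30),
                       ses_quintile = rep(c("1", "2", "unknown"), 20))
  coh <- cohort(pts, make_hospitals("H1"))
  expect_warning(m <- fit_outcome_model(coh, covariates = "ses_quintile"),
                 "unknown SES")
  expect_equal(glance(m)$n, 40)
  m2 <- fit_outcome_model(coh, covariates = "ses_quintile",
                          ses_unknown = "category")
  expect_equal(glance(m2)$n, 60)
  expect_true("ses_quintileunknown" %in% tidy(m2)$term)
})
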