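test_that("default study-like generation reproduces the published aggregates", {
  sim <- generate_cohort(generator_config(seed = 1))
  coh <- sim$cohort
  expect_equal(nrow(coh$patients), 2801)
  expect_equal(nrow(coh$hospitals), 72)
  expect_equal(sum(sim$truth$hospital_effects$size), 2801)
  # overall treated fraction calibrated to 66%, within sampling error
  expect_lt(abs(mean(coh$patients$treated) - 0.66), 0.02)
  # heavy-tailed volume profile leaves some low-volume hospitals
  expect_gt(sum(sim$truth$hospital_effects$size < 10), 0)
})

test_that("generation is deterministic given config and seed, and files round-trip", {
  cfg <- generator_config(n_hospitals = 8, n_patients = 300, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort$patients, b$cohort$patients)
  expect_identical(a$cohort$hospitals, b$cohort$hospitals)
  expect_identical(a$truth$hospital_effects, b$truth$hospital_effects)

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  f3 <- withr::local_tempfile(fileext = ".csv")
  f4 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a$cohort, f1, f2)
  write_cohort(b$cohort, f3, f4)
  expect_identical(readLines(f1), readLines(f3))
  expect_identical(readLines(f2), readLines(f4))
})

test_that("degenerate and boundary configurations behave as the model implies", {
  # base_rate = 1 with no noise: everyone treated
  cfg <- generator_config(n_hospitals = 4, n_patients = 100, base_rate = 1,
                          covariate_log_odds = list(), seed = 2)
  expect_true(all(generate_cohort(cfg)$cohort$patients$treated == 1))

  # more hospitals than patients is infeasible
  expect_error(generator_config(n_hospitals = 10, n_patients = 5),
               class = "act_config_error")

  # marginals must sum to one over the full level set
  expect_error(
    generator_config(covariate_marginals = list(sex = c(F = 0.7, M = 0.6))),
    class = "act_config_error")
})

test_that("per-hospital rates under the uniform null stay within binomial bounds", {
  cfg <- generator_config(n_hospitals = 72, n_patients = 1e5, base_rate = 0.5,
                          hospital_size_profile = "uniform",
                          covariate_log_odds = list(), hospital_sd = 0,
                          seed = 7)
  r <- hospital_rates(generate_cohort(cfg)$cohort)
  se <- sqrt(0.25 / r$n)
  expect_true(all(abs(r$rate - 0.5) <= 3.5 * se))
  expect_lt(abs(pooled_rate(r)$rate - 0.5), 0.005)
})

test_that("intercept calibration matches closed forms and large-n simulation", {
  # no covariate effects: the intercept is exactly logit(base_rate)
  cfg0 <- generator_config(covariate_log_odds = list())
  expect_equal(calibrate_intercept(cfg0), qlogis(0.66), tolerance = 1e-8)

  # symmetric effects at base_rate 0.5: intercept 0 by symmetry
  cfg_sym <- generator_config(
    base_rate = 0.5,
    covariate_marginals = list(sex = c(F = 0.5, M = 0.5)),
    covariate_log_odds = list(sex = c(F = -0.8, M = 0.8)))
  expect_equal(calibrate_intercept(cfg_sym), 0, tolerance = 1e-8)

  # with the default age/comorbidity gradients the realized marginal rate
  # converges to base_rate
  cfg_big <- generator_config(n_hospitals = 50, n_patients = 4e5,
                              hospital_size_profile = "uniform", seed = 11)
  sim <- generate_cohort(cfg_big)
  expect_lt(abs(mean(sim$cohort$patients$treated) - 0.66), 0.005)

  # calibration also integrates over hospital random intercepts
  cfg_re <- generator_config(n_hospitals = 200, n_patients = 2e5,
                             hospital_size_profile = "uniform",
                             hospital_sd = 1, seed = 12)
  expect_lt(abs(mean(generate_cohort(cfg_re)$cohort$patients$treated) - 0.66),
            0.01)
})

test_that("generated covariate frequencies match the configured marginals", {
  marg <- table1_marginals()
  for (seed in c(3, 14)) {
    pts <- generate_cohort(generator_config(seed = seed))$cohort$patients
    for (col in names(marg)) {
      m <- marg[[col]]
      obs <- table(factor(pts[[col]], levels = names(m)))
      keep <- m > 0
      p <- suppressWarnings(stats::chisq.test(obs[keep], p = m[keep] / sum(m[keep]))$p.value)
      expect_gt(p, 0.01)
    }
  }
})

test_that("forced small-hospital count and custom weights are honoured", {
  cfg <- generator_config(n_small_hospitals = 15, seed = 5)
  sim <- generate_cohort(cfg)
  expect_equal(sum(sim$truth$hospital_effects$size < 10), 15)
  expect_equal(sum(sim$truth$hospital_effects$size), 2801)

  w <- c(5, 1, 1, 1)
  cfg2 <- generator_config(n_hospitals = 4, n_patients = 80,
                           hospital_size_profile = w, seed = 5)
  sizes <- generate_cohort(cfg2)$truth$hospital_effects$size
  expect_equal(sizes, c(50L, 10L, 10L, 10L))
})

test_that("hospital case-mix skew shifts level distributions between hospitals", {
  cfg <- generator_config(case_mix_skew_covariate = "age_group",
                          case_mix_skew_sd = 0.8, seed = 9)
  sim <- generate_cohort(cfg)
  pts <- sim$cohort$patients
  skew <- sim$truth$hospital_effects
  # hospitals with positive tilt should see older patients on average
  age_idx <- as.integer(factor(pts$age_group, levels = cohort_levels()$age_group))
  mean_age <- tapply(age_idx, pts$hospital_id, mean)
  big <- skew$size >= 20
  expect_gt(stats::cor(skew$case_mix_skew[big],
                       mean_age[skew$hospital_id[big]]), 0.5)
})
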