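test_that("small-hospital exclusion keeps the boundary and conserves patients", {
  coh <- make_count_cohort(n = c(9, 10, 11), k = c(5, 6, 7))
  r <- hospital_rates(coh)
  ex <- exclude_small_hospitals(r, min_cases = 10)
  expect_equal(nrow(ex$rates), 2)           # n = 10 retained
  expect_equal(ex$excluded$n, 9L)
  expect_equal(ex$report$patients_excluded, 9L)
  expect_equal(ex$report$patients_remaining, 21L)
  expect_equal(ex$report$patients_excluded + ex$report$patients_remaining,
               sum(r$n))

  # min_cases = 1 excludes nothing
  ex1 <- exclude_small_hospitals(r, min_cases = 1)
  expect_equal(nrow(ex1$rates), 3)
  expect_error(exclude_small_hospitals(r, min_cases = 100), "below")
})

test_that("the pared-mean benchmark matches the worked five-hospital example", {
  coh <- make_count_cohort(n = c(20, 30, 50, 60, 40),
                           k = c(18, 24, 30, 36, 20))
  r <- hospital_rates(coh)
  b <- pared_mean_benchmark(r, fraction = 0.10)
  # top hospital (rate 0.90, n = 20) alone reaches 10% of 200
  expect_equal(nrow(b$selected), 1)
  expect_equal(b$benchmark_rate, 18 / 20)
  expect_equal(b$nonbenchmark_rate, 110 / 180, tolerance = 1e-9)
  expect_equal(b$benchmark_k + b$nonbenchmark_k, sum(r$k))
  expect_equal(b$benchmark_n + b$nonbenchmark_n, sum(r$n))
  expect_equal(b$shortfall_percent,
               (0.9 - 0.64) / 0.9 * 100, tolerance = 1e-9)

  # fraction 1 selects everyone; the benchmark is the pooled rate
  b_all <- pared_mean_benchmark(r, fraction = 1)
  expect_equal(nrow(b_all$selected), 5)
  expect_equal(b_all$benchmark_rate, pooled_rate(r)$rate)
  expect_equal(b_all$shortfall_percent, 0)
})

test_that("pared-mean selection equals exhaustive prefix search", {
  set.seed(77)
  for (i in 1:25) {
    h <- sample(3:12, 1)
    n <- sample(5:60, h, replace = TRUE)
    k <- rbinom(h, n, runif(1, 0.3, 0.9))
    frac <- runif(1, 0.05, 0.6)
    coh <- make_count_cohort(n = n, k = pmin(k, n))
    r <- hospital_rates(coh)
    b <- pared_mean_benchmark(r, fraction = frac)
    expect_setequal(b$selected$hospital_id, prefix_oracle(r, frac))
    # descending-rank pooling: benchmark never below non-benchmark
    if (b$nonbenchmark_n > 0) {
      expect_gte(b$benchmark_rate, b$nonbenchmark_rate)
    }
    expect_gte(b$benchmark_rate, pooled_rate(r)$rate)
  }
})

test_that("rate ties break deterministically by volume then id", {
  coh <- make_count_cohort(n = c(20, 40, 20), k = c(10, 20, 10),
                           hospital_id = c("HB", "HC", "HA"))
  r <- hospital_rates(coh)
  b <- pared_mean_benchmark(r, fraction = 0.4)
  expect_equal(b$selected$hospital_id, "HC")     # largest n first
  b2 <- pared_mean_benchmark(r, fraction = 0.7)
  expect_equal(b2$selected$hospital_id, c("HC", "HA"))  # then id order
})

test_that("shortfall follows its defining formula exactly", {
  expect_equal(round(shortfall(81, 66), 1), 18.5)
  expect_equal(round(shortfall(74, 66), 1), 10.8)
  for (x in c(1, 37.5, 66, 100)) expect_equal(shortfall(x, x), 0)
  expect_equal(shortfall(0.74, 0.66), shortfall(74, 66))  # scale-invariant
  expect_lt(shortfall(80, 90), 0)
  # strictly decreasing in the actual rate
  a <- seq(10, 90, by = 10)
  expect_true(all(diff(shortfall(80, a)) < 0))
  expect_error(shortfall(0, 10), "positive")
})

test_that("criterion-based benchmark responds to a real criterion effect and rejects degenerate input", {
  set.seed(88)
  h <- 20
  ids <- sprintf("H%02d", 1:h)
  flag <- rep(c(1L, 0L), c(6, 14))
  n <- rep(60, h)
  k <- rbinom(h, n, ifelse(flag == 1, 0.78, 0.60))
  coh <- make_count_cohort(n = n, k = k, hospital_id = ids)
  coh$hospitals$cancer_centre <- flag
  b <- suppressWarnings(cbb_benchmark(coh, "cancer_centre",
                                      covariates = character(0),
                                      boot_reps = 200, seed = 1))
  expect_gt(b$benchmark_rate, b$comparison_rate)
  expect_gt(b$shortfall_percent, 0)
  expect_true(b$benchmark_ci[1] <= b$benchmark_rate &
              b$benchmark_rate <= b$benchmark_ci[2])

  coh$hospitals$cancer_centre <- 0L
  coh2 <- cohort(coh$patients, coh$hospitals[1:4])
  expect_error(cbb_benchmark(coh2, "cancer_centre",
                             covariates = character(0)), "constant")
})

test_that("adjusted pared-mean ranking pools volume-weighted adjusted rates", {
  sim <- generate_cohort(generator_config(seed = 41))
  m <- suppressWarnings(fit_outcome_model(sim$cohort))
  adj <- adjusted_hospital_rates(sim$cohort, m, bootstrap_reps = 300, seed = 3)
  eligible <- adj[adj$n >= 10, ]
  attr(eligible, "draws") <- attr(adj, "draws")
  b <- pared_mean_benchmark(eligible, fraction = 0.10, rank_by = "adjusted")
  expect_equal(b$method, "abc_adjusted")
  sel <- eligible[eligible$hospital_id %in% b$selected$hospital_id, ]
  expect_equal(b$benchmark_rate, sum(sel$n * sel$adjusted) / sum(sel$n),
               tolerance = 1e-9)
  expect_true(b$benchmark_ci[1] <= b$benchmark_rate &
              b$benchmark_rate <= b$benchmark_ci[2])
})

test_that("under pure chance the pared-mean benchmark overshoots while CBB does not", {
  res <- abc_overestimation_experiment(generator_config(), replicates = 30,
                                       seed = 7)
  expect_equal(nrow(res), 30)
  expect_gt(mean(res$abc_benchmark), 0.66)
  expect_gt(mean(res$abc_shortfall), 0)
  expect_lt(abs(mean(res$cbb_shortfall)), 3)
  expect_error(
    abc_overestimation_experiment(generator_config(hospital_sd = 0.5),
                                  replicates = 2),
    "hospital_sd")
})

test_that("with hospital-level case-mix skew the adjusted benchmark is the smaller one", {
  cfg <- generator_config(case_mix_skew_covariate = "age_group",
                          case_mix_skew_sd = 0.6)
  res <- abc_overestimation_experiment(cfg, replicates = 20, seed = 19)
  expect_lt(mean(res$abc_adj_benchmark), mean(res$abc_benchmark))
})
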