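#' Exclude low-volume hospitals before benchmarking
#'
#' Removes hospitals with fewer than `min_cases` study cases (default 10, the
#' conventional disclosure/stability threshold; a hospital with exactly
#' `min_cases` is retained) and reports exactly what was excluded. The pooled
#' rate of the returned table is recomputed over the eligible hospitals.
#'
#' @param rates An `act_rates` tibble from [hospital_rates()].
#' @param min_cases Minimum case volume (default 10).
#' @return A list: `rates` (eligible hospitals, class `act_rates`),
#'   `excluded` (tibble of removed hospitals), and `report` (hospitals
#'   excluded, patients excluded, patients remaining).
#' @export
exclude_small_hospitals <- function(rates, min_cases = 10L) {
  keep <- rates$n >= min_cases
  if (!any(keep)) abort("all hospitals fall below min_cases")
  excluded <- tibble::as_tibble(rates[!keep, c("hospital_id", "n", "k", "rate")])
  eligible <- rates[keep, ]
  pool <- attr(rates, "pooled")
  pci <- binomial_ci(sum(eligible$k), sum(eligible$n), conf = pool$conf,
                     method = pool$ci_method)
  attr(eligible, "pooled") <- list(
    n = sum(eligible$n), k = sum(eligible$k),
    rate = sum(eligible$k) / sum(eligible$n),
    ci_low = pci$ci_low, ci_high = pci$ci_high,
    conf = pool$conf, ci_method = pool$ci_method
  )
  list(
    rates = eligible,
    excluded = excluded,
    report = list(
      hospitals_excluded = sum(!keep),
      patients_excluded = sum(excluded$n),
      patients_remaining = sum(eligible$n)
    )
  )
}

#' Utilization shortfall relative to a benchmark
#'
#' `(benchmark - actual) / benchmark * 100`: the relative gap between the
#' benchmark rate and achieved utilization, in percent of the benchmark.
#' Negative when the actual rate exceeds the benchmark. Scale-invariant, so
#' the two rates may be given as percentages or proportions (consistently).
#'
#' @param benchmark_rate,actual_rate Rates on a common scale; vectorized.
#' @return Shortfall in percent.
#' @export
#' @examples
#' shortfall(81, 66)  # 18.5...
shortfall <- function(benchmark_rate, actual_rate) {
  if (any(benchmark_rate <= 0)) abort("benchmark rate must be positive")
  (benchmark_rate - actual_rate) / benchmark_rate * 100
}

# Deterministic pared-mean ordering: descending rate, ties broken by larger
# volume (more evidence), then lexicographic hospital id.
pared_mean_order <- function(rank_rate, n, hospital_id) {
  order(-rank_rate, -n, hospital_id)
}

#' Pared-mean (achievable benchmarks of care) benchmark rate
#'
#' Ranks hospitals by descending rate and accumulates them, best first, until
#' the selected hospitals together hold at least `fraction` (default 10%) of
#' the eligible population; the benchmark rate is the pooled rate over the
#' selected hospitals. Because the stopping rule takes the first prefix
#' reaching the threshold, the selected share may slightly exceed the
#' fraction. Ties in rate are broken by larger volume, then hospital id, so
#' the selection is deterministic.
#'
#' With `rank_by = "adjusted"` (an [adjusted_hospital_rates()] table),
#' ranking and pooling use the case-mix-adjusted rates: the benchmark is the
#' volume-weighted mean adjusted rate of the selected hospitals, and its
#' interval is the percentile interval of the same weighted mean across the
#' bootstrap draws when those are attached.
#'
#' @param rates An `act_rates` table (post-exclusion; see
#'   [exclude_small_hospitals()]) or, for `rank_by = "adjusted"`, an
#'   `act_adjusted_rates` table.
#' @param fraction Target population share of the benchmark subset, in (0, 1]
#'   (default 0.10). The denominator is the population of the table supplied
#'   (i.e. post-exclusion by default).
#' @param rank_by `"observed"` or `"adjusted"`.
#' @param conf,ci_method Interval settings for pooled-count intervals.
#' @return An object of class `act_benchmark` (see [tidy()]/[glance()]):
#'   selected hospitals, benchmark and non-benchmark rates with intervals,
#'   the comparison (provincial) rate and the percent shortfall against it.
#' @export
pared_mean_benchmark <- function(rates, fraction = 0.10,
                                 rank_by = c("observed", "adjusted"),
                                 conf = 0.95,
                                 ci_method = c("wilson", "wald")) {
  rank_by <- match.arg(rank_by)
  ci_method <- match.arg(ci_method)
  if (nrow(rates) == 0) abort("empty rate table")
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  rate_col <- if (rank_by == "adjusted") "adjusted" else "rate"
  if (!rate_col %in% names(rates)) {
    abort(sprintf("rate table has no '%s' column for rank_by = '%s'",
                  rate_col, rank_by))
  }
  ord <- pared_mean_order(rates[[rate_col]], rates$n, rates$hospital_id)
  sorted <- rates[ord, ]
  total_n <- sum(sorted$n)
  cum_n <- cumsum(sorted$n)
  n_sel <- which(cum_n >= fraction * total_n)[1]
  sel <- sorted[seq_len(n_sel), ]
  rest <- sorted[-seq_len(n_sel), ]

  pool_rate <- sum(sorted$k) / total_n

  pooled_block <- function(d) {
    if (nrow(d) == 0) {
      return(list(n = 0L, k = 0L, rate = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_))
    }
    if (rank_by == "adjusted") {
      r <- sum(d$n * d[[rate_col]]) / sum(d$n)
      ci <- c(NA_real_, NA_real_)
      draws <- attr(rates, "draws")
      if (!is.null(draws)) {
        w <- draws[, d$hospital_id, drop = FALSE] %*% (d$n / sum(d$n))
        a <- (1 - conf) / 2
        ci <- unname(quantile(w, c(a, 1 - a), na.rm = TRUE))
      }
      list(n = sum(d$n), k = sum(d$k), rate = r, ci_low = ci[1], ci_high = ci[2])
    } else {
      ci <- binomial_ci(sum(d$k), sum(d$n), conf = conf, method = ci_method)
      list(n = sum(d$n), k = sum(d$k), rate = sum(d$k) / sum(d$n),
           ci_low = ci$ci_low, ci_high = ci$ci_high)
    }
  }
  bm <- pooled_block(sel)
  nb <- pooled_block(rest)

  structure(list(
    method = if (rank_by == "adjusted") "abc_adjusted" else "abc_unadjusted",
    selected = tibble::as_tibble(sel),
    fraction = fraction,
    selected_share = bm$n / total_n,
    benchmark_n = bm$n, benchmark_k = bm$k, benchmark_rate = bm$rate,
    benchmark_ci = c(bm$ci_low, bm$ci_high),
    nonbenchmark_n = nb$n, nonbenchmark_k = nb$k, nonbenchmark_rate = nb$rate,
    nonbenchmark_ci = c(nb$ci_low, nb$ci_high),
    comparison_rate = pool_rate,
    comparison_basis = "provincial (eligible population)",
    shortfall_percent = shortfall(bm$rate, pool_rate),
    conf = conf
  ), class = "act_benchmark")
}

#' Criterion-based benchmark rate
#'
#' The benchmark is the case-mix-standardized treatment rate in the
#' subpopulation of hospitals meeting an optimal-access criterion (e.g.
#' comprehensive cancer centres): the marginal-standardized rate at criterion
#' level 1 from [factor_effect()]. The shortfall compares it to the
#' provincial rate.
#'
#' @inheritParams factor_effect
#' @param criterion A binary hospital attribute naming the criterion.
#' @return An `act_benchmark` with `method = "cbb"`.
#' @export
cbb_benchmark <- function(cohort, criterion = "cancer_centre",
                          covariates = act_covariates(), boot_reps = 1000L,
                          seed = NULL, conf = 0.95,
                          ses_unknown = c("drop", "category")) {
  fe <- factor_effect(cohort, criterion, covariates = covariates,
                      boot_reps = boot_reps, seed = seed, conf = conf,
                      ses_unknown = ses_unknown)
  lv <- fe$levels
  row1 <- lv[lv$level == "1", ]
  row0 <- lv[lv$level == "0", ]
  provincial <- (row1$k + row0$k) / (row1$n + row0$n)
  sel_ids <- cohort$hospitals$hospital_id[cohort$hospitals[[criterion]] == 1]
  structure(list(
    method = "cbb",
    criterion = criterion,
    selected = tibble::tibble(hospital_id = sel_ids),
    benchmark_n = row1$n, benchmark_k = row1$k,
    benchmark_rate = row1$adj_rate,
    benchmark_ci = c(row1$adj_ci_low, row1$adj_ci_high),
    nonbenchmark_n = row0$n, nonbenchmark_k = row0$k,
    nonbenchmark_rate = row0$adj_rate,
    nonbenchmark_ci = c(row0$adj_ci_low, row0$adj_ci_high),
    comparison_rate = provincial,
    comparison_basis = "provincial (full cohort)",
    shortfall_percent = shortfall(row1$adj_rate, provincial),
    factor_effect = fe,
    conf = conf
  ), class = "act_benchmark")
}

#' @export
print.act_benchmark <- function(x, ...) {
  cat(sprintf("<act_benchmark> method %s\n", x$method))
  cat(sprintf("  benchmark: %d hospitals, %d/%d = %.3f (%.3f-%.3f)\n",
              nrow(x$selected), x$benchmark_k, x$benchmark_n,
              x$benchmark_rate, x$benchmark_ci[1], x$benchmark_ci[2]))
  if (x$nonbenchmark_n > 0) {
    cat(sprintf("  non-benchmark: %d/%d = %.3f (%.3f-%.3f)\n",
                x$nonbenchmark_k, x$nonbenchmark_n, x$nonbenchmark_rate,
                x$nonbenchmark_ci[1], x$nonbenchmark_ci[2]))
  }
  cat(sprintf("  comparison rate %.3f [%s]; shortfall %.1f%%\n",
              x$comparison_rate, x$comparison_basis, x$shortfall_percent))
  invisible(x)
}

#' @rdname pared_mean_benchmark
#' @param x An `act_benchmark`.
#' @param ... Unused.
#' @method tidy act_benchmark
#' @export
tidy.act_benchmark <- function(x, ...) {
  tibble::tibble(
    group = c("benchmark", "non-benchmark"),
    n = c(x$benchmark_n, x$nonbenchmark_n),
    k = c(x$benchmark_k, x$nonbenchmark_k),
    rate = c(x$benchmark_rate, x$nonbenchmark_rate),
    ci_low = c(x$benchmark_ci[1], x$nonbenchmark_ci[1]),
    ci_high = c(x$benchmark_ci[2], x$nonbenchmark_ci[2])
  )
}

#' @rdname pared_mean_benchmark
#' @method glance act_benchmark
#' @export
glance.act_benchmark <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_selected = nrow(x$selected),
    benchmark_rate = x$benchmark_rate,
    benchmark_ci_low = x$benchmark_ci[1],
    benchmark_ci_high = x$benchmark_ci[2],
    nonbenchmark_rate = x$nonbenchmark_rate,
    comparison_rate = x$comparison_rate,
    shortfall_percent = x$shortfall_percent
  )
}

#' Pared-mean overestimation under the pure-chance null
#'
#' Quantifies the selection bias of the pared-mean benchmark when hospital
#' rate variation is entirely random: for each replicate a cohort is
#' generated from `config` (which must have `hospital_sd = 0`), the
#' unadjusted and case-mix-adjusted pared-mean benchmarks and the
#' criterion-based benchmark are computed, and each is compared to the true
#' underlying rate. With hospitals of finite size the unadjusted pared-mean
#' benchmark exceeds the true rate in expectation (the top ranks are
#' selected partly on binomial noise), while the criterion-based benchmark
#' is centred on it.
#'
#' @param config An [generator_config()] with `hospital_sd = 0`.
#' @param replicates Number of replicate cohorts (default 200).
#' @param seed Master seed; replicate seeds are derived from it.
#' @param fraction,min_cases Pared-mean settings.
#' @param criterion Hospital flag for the criterion-based benchmark
#'   (default `"cancer_centre"`); `NULL` skips it.
#' @param adjust Also compute the adjusted pared-mean benchmark (default
#'   TRUE).
#' @return A tibble, one row per replicate: benchmark rates and shortfalls
#'   (vs the true `base_rate` for the pared-mean methods, vs the realized
#'   provincial rate for the criterion-based method).
#' @export
abc_overestimation_experiment <- function(config, replicates = 200L, seed = 1L,
                                          fraction = 0.10, min_cases = 10L,
                                          criterion = "cancer_centre",
                                          adjust = TRUE) {
  if (config$hospital_sd != 0) {
    abort("the overestimation experiment is defined under hospital_sd = 0")
  }
  purrr::map_dfr(seq_len(replicates), function(r) {
    cfg <- config
    cfg$seed <- as.integer((as.numeric(seed) * 7919 + r) %% 2147483647)
    sim <- generate_cohort(cfg)
    rates <- hospital_rates(sim$cohort)
    eligible <- exclude_small_hospitals(rates, min_cases = min_cases)$rates
    abc <- pared_mean_benchmark(eligible, fraction = fraction)
    out <- tibble::tibble(
      replicate = r,
      seed = cfg$seed,
      pooled_rate = pooled_rate(rates)$rate,
      abc_benchmark = abc$benchmark_rate,
      abc_shortfall = shortfall(abc$benchmark_rate, config$base_rate)
    )
    if (adjust) {
      model <- suppressWarnings(fit_outcome_model(sim$cohort))
      adj <- adjusted_hospital_rates(sim$cohort, model, bootstrap_reps = 0L)
      adj_eligible <- adj[adj$n >= min_cases, ]
      abc_adj <- pared_mean_benchmark(adj_eligible, fraction = fraction,
                                      rank_by = "adjusted")
      out$abc_adj_benchmark <- abc_adj$benchmark_rate
      out$abc_adj_shortfall <- shortfall(abc_adj$benchmark_rate, config$base_rate)
    }
    if (!is.null(criterion)) {
      cbb <- suppressWarnings(cbb_benchmark(sim$cohort, criterion = criterion,
                                            boot_reps = 0L))
      out$cbb_benchmark <- cbb$benchmark_rate
      out$cbb_shortfall <- cbb$shortfall_percent
    }
    out
  })
}
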