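#' Binomial confidence interval
#'
#' Wilson score interval by default; Wald available for comparability with
#' reports that print symmetric intervals.
#'
#' @param k,n Numerator and denominator (vectorized).
#' @param conf Confidence level (default 0.95).
#' @param method `"wilson"` or `"wald"`.
#' @return Tibble with columns `ci_low`, `ci_high`, clamped to `[0, 1]`.
#' @export
binomial_ci <- function(k, n, conf = 0.95, method = c("wilson", "wald")) {
  method <- match.arg(method)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  if (method == "wilson") {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- centre - half
    hi <- centre + half
  } else {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half
    hi <- p + half
  }
  tibble::tibble(ci_low = pmax(0, lo), ci_high = pmin(1, hi))
}

#' Hospital-specific treatment rates
#'
#' One row per hospital with numerator `k`, denominator `n`, `rate = k/n` and
#' a binomial confidence interval; the pooled (provincial) rate over the same
#' hospitals is attached as an attribute and available via [pooled_rate()].
#'
#' @param cohort An `act_cohort` or a patient-level data frame with columns
#'   `hospital_id` and `treated`.
#' @param min_cases Keep hospitals with at least this many cases (default 1).
#' @param conf Confidence level for rate intervals.
#' @param ci_method Passed to [binomial_ci()].
#' @return A tibble of class `act_rates`, sorted by `hospital_id`.
#' @export
#' @examples
#' pts <- tibble::tibble(hospital_id = rep(c("A", "B"), c(10, 20)),
#'                       treated = rep(c(1, 0, 1, 0), c(5, 5, 10, 10)))
#' hospital_rates(pts)
hospital_rates <- function(cohort, min_cases = 1L, conf = 0.95,
                           ci_method = c("wilson", "wald")) {
  ci_method <- match.arg(ci_method)
  patients <- cohort_patients(cohort)
  if (nrow(patients) == 0) abort("cohort is empty")
  rates <- patients %>%
    dplyr::group_by(.data$hospital_id) %>%
    dplyr::summarise(n = dplyr::n(), k = sum(.data$treated), .groups = "drop") %>%
    dplyr::filter(.data$n >= min_cases) %>%
    dplyr::arrange(.data$hospital_id) %>%
    dplyr::mutate(rate = .data$k / .data$n)
  ci <- binomial_ci(rates$k, rates$n, conf = conf, method = ci_method)
  rates <- dplyr::bind_cols(rates, ci)
  pooled_k <- sum(rates$k)
  pooled_n <- sum(rates$n)
  pci <- binomial_ci(pooled_k, pooled_n, conf = conf, method = ci_method)
  attr(rates, "pooled") <- list(n = pooled_n, k = pooled_k,
                                rate = pooled_k / pooled_n,
                                ci_low = pci$ci_low, ci_high = pci$ci_high,
                                conf = conf, ci_method = ci_method)
  class(rates) <- c("act_rates", class(rates))
  rates
}

#' Pooled rate attached to a rate table
#'
#' @param rates An `act_rates` tibble from [hospital_rates()].
#' @return Named list: `n`, `k`, `rate`, `ci_low`, `ci_high`.
#' @export
pooled_rate <- function(rates) {
  p <- attr(rates, "pooled")
  if (is.null(p)) abort("no pooled rate attribute; was this made by hospital_rates()?")
  p
}

#' Coefficient of variation of hospital rates
#'
#' The ratio of the standard deviation to the mean of the hospital-specific
#' rates, each hospital counting as one observation (unweighted), with the
#' sample (n-1) standard deviation.
#'
#' @param rates An `act_rates` tibble or a numeric vector of rates.
#' @return The CV as a unitless ratio.
#' @export
#' @examples
#' coefficient_of_variation(c(0.6, 0.7, 0.8))  # 0.142857...
coefficient_of_variation <- function(rates) {
  r <- if (is.numeric(rates)) rates else rates$rate
  if (length(r) < 2) abort("CV requires at least 2 hospitals")
  m <- mean(r)
  if (m == 0) abort("CV undefined: mean rate is 0", class = "act_degenerate_cv")
  sd(r) / m
}

#' Monte Carlo null distribution of the CV under pure chance
#'
#' Simulates the coefficient of variation of hospital rates under the null in
#' which every hospital shares the same treatment probability `p`: each
#' iteration draws \eqn{k_h \sim \mathrm{Binomial}(n_h, p)} independently for
#' each hospital and computes the CV across the simulated rates. Iterations
#' whose mean rate is 0 leave the CV undefined; they are excluded from the
#' distribution and counted.
#'
#' @param hospital_ns Integer vector of hospital case counts.
#' @param p Common treatment probability.
#' @param iterations Number of simulated cohorts (default 1000).
#' @param seed Optional seed for reproducibility.
#' @param conf Level of the percentile interval on the simulated CVs.
#' @return An object of class `act_cv_null`: `simulated_cvs`, `expected_cv`
#'   (their mean), `expected_ci` (percentile interval), `n_iterations`,
#'   `n_degenerate`, and the inputs.
#' @export
simulate_null_cv <- function(hospital_ns, p, iterations = 1000L, seed = NULL,
                             conf = 0.95) {
  hospital_ns <- as.integer(hospital_ns)
  if (any(hospital_ns < 1)) abort("all hospital sizes must be >= 1")
  if (length(hospital_ns) < 2) abort("need at least 2 hospitals")
  if (p < 0 || p > 1) abort("p must be a probability")
  iterations <- as.integer(iterations)
  if (iterations < 1) abort("iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  h <- length(hospital_ns)
  k <- matrix(rbinom(iterations * h, size = rep(hospital_ns, each = iterations),
                     prob = p), nrow = iterations)
  r <- sweep(k, 2, hospital_ns, `/`)
  means <- rowMeans(r)
  sds <- apply(r, 1, sd)
  degenerate <- means == 0
  cvs <- sds[!degenerate] / means[!degenerate]
  if (length(cvs) == 0) {
    abort("all iterations degenerate (mean rate 0); p too close to 0",
          class = "act_degenerate_cv")
  }
  structure(list(
    simulated_cvs = cvs,
    expected_cv = mean(cvs),
    expected_ci = unname(quantile(cvs, c((1 - conf) / 2, 1 - (1 - conf) / 2))),
    n_iterations = iterations,
    n_degenerate = sum(degenerate),
    p = p, hospital_ns = hospital_ns, conf = conf
  ), class = "act_cv_null")
}

#' Nonrandom component of rate variation
#'
#' The observed CV minus the chance-expected CV; may be negative when the
#' observed variation falls below its null expectation.
#'
#' @param observed_cv,expected_cv CVs as ratios (or both as percentages).
#' @return Difference on the same scale as the inputs.
#' @export
#' @examples
#' nonrandom_component(0.156, 0.141)  # 0.015
nonrandom_component <- function(observed_cv, expected_cv) {
  observed_cv - expected_cv
}

#' Decompose inter-hospital rate variation into random and systematic parts
#'
#' Computes the observed CV of hospital-specific rates, simulates the CV
#' expected by chance alone (every hospital assigned the pooled rate, actual
#' hospital denominators, [simulate_null_cv()]), and reports the difference
#' as the nonrandom component together with whether the observed CV lies
#' inside the null percentile interval.
#'
#' @inheritParams hospital_rates
#' @param iterations Monte Carlo iterations (default 1000).
#' @param seed Optional seed.
#' @param conf Level of the null percentile interval.
#' @return An object of class `act_cv_decomposition` with fields
#'   `observed_cv`, `expected_cv`, `expected_ci`, `nonrandom_component`,
#'   `observed_within_ci`, `simulated_cvs`, `n_iterations`, `n_degenerate`,
#'   `pooled_rate`, `n_hospitals`.
#' @export
decompose_variation <- function(cohort, iterations = 1000L, seed = NULL,
                                min_cases = 1L, conf = 0.95) {
  rates <- hospital_rates(cohort, min_cases = min_cases, conf = conf)
  observed <- coefficient_of_variation(rates)
  null <- simulate_null_cv(rates$n, pooled_rate(rates)$rate,
                           iterations = iterations, seed = seed, conf = conf)
  structure(list(
    observed_cv = observed,
    expected_cv = null$expected_cv,
    expected_ci = null$expected_ci,
    nonrandom_component = nonrandom_component(observed, null$expected_cv),
    observed_within_ci = observed >= null$expected_ci[1] &&
      observed <= null$expected_ci[2],
    simulated_cvs = null$simulated_cvs,
    n_iterations = null$n_iterations,
    n_degenerate = null$n_degenerate,
    pooled_rate = pooled_rate(rates)$rate,
    n_hospitals = nrow(rates),
    conf = conf
  ), class = "act_cv_decomposition")
}

#' @export
print.act_cv_decomposition <- function(x, ...) {
  cat(sprintf(
    paste0("<act_cv_decomposition> %d hospitals, pooled rate %.3f\n",
           "  observed CV %.3f; expected CV %.3f (%d%% CI %.3f-%.3f)\n",
           "  nonrandom component %.3f; observed %s the null interval\n"),
    x$n_hospitals, x$pooled_rate, x$observed_cv, x$expected_cv,
    round(100 * x$conf), x$expected_ci[1], x$expected_ci[2],
    x$nonrandom_component,
    if (x$observed_within_ci) "inside" else "outside"))
  invisible(x)
}

#' @rdname decompose_variation
#' @param x An `act_cv_decomposition`.
#' @param ... Unused.
#' @method tidy act_cv_decomposition
#' @export
tidy.act_cv_decomposition <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$simulated_cvs),
                 simulated_cv = x$simulated_cvs)
}

#' @rdname decompose_variation
#' @method glance act_cv_decomposition
#' @export
glance.act_cv_decomposition <- function(x, ...) {
  tibble::tibble(
    observed_cv = x$observed_cv, expected_cv = x$expected_cv,
    expected_ci_low = x$expected_ci[1], expected_ci_high = x$expected_ci[2],
    nonrandom_component = x$nonrandom_component,
    observed_within_ci = x$observed_within_ci,
    n_hospitals = x$n_hospitals, n_iterations = x$n_iterations,
    n_degenerate = x$n_degenerate, pooled_rate = x$pooled_rate
  )
}

#' @rdname decompose_variation
#' @param object An `act_cv_decomposition`.
#' @method autoplot act_cv_decomposition
#' @export
autoplot.act_cv_decomposition <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$simulated_cv)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_cv,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$expected_ci,
                        linetype = "dashed") +
    ggplot2::labs(x = "Simulated CV under the binomial null", y = "Iterations",
                  title = "Observed CV (red) against its chance-only distribution")
}

#' Plot hospital rates against the provincial mean
#'
#' Scatter of hospital-specific rates by case volume with the pooled rate and
#' its confidence band as horizontal lines (a classic provider-profiling
#' display), or hospitals ranked by descending rate.
#'
#' @param object An `act_rates` tibble.
#' @param type `"volume"` (rate vs case count) or `"ranked"` (descending
#'   rates by rank).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot act_rates
#' @export
autoplot.act_rates <- function(object, type = c("volume", "ranked"), ...) {
  type <- match.arg(type)
  pool <- pooled_rate(object)
  if (type == "volume") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$rate)) +
      ggplot2::geom_hline(yintercept = pool$rate, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = c(pool$ci_low, pool$ci_high),
                          linetype = "dashed", colour = "steelblue") +
      ggplot2::geom_point(shape = 5) +
      ggplot2::labs(x = "Hospital case volume", y = "Treatment rate")
  } else {
    ranked <- dplyr::arrange(tibble::as_tibble(object), dplyr::desc(.data$rate))
    ranked$rank <- seq_len(nrow(ranked))
    ggplot2::ggplot(ranked, ggplot2::aes(x = .data$rank, y = .data$rate)) +
      ggplot2::geom_col(fill = "grey70") +
      ggplot2::geom_hline(yintercept = pool$rate, colour = "steelblue") +
      ggplot2::labs(x = "Hospital rank", y = "Treatment rate")
  }
}
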