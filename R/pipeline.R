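#' Configuration for a full benchmarking run
#'
#' Exactly one input source must be given: either the two cohort file paths
#' or a generator configuration.
#'
#' @param out_dir Output directory for all artifacts (created if absent).
#' @param patients_path,hospitals_path Paths to an on-disk cohort.
#' @param generator An [generator_config()] to synthesize the cohort instead.
#' @param stages Character vector of stages to run, a subset of
#'   `c("summary", "rates", "mc-null", "adjust", "factors", "abc", "cbb")`,
#'   or `"all"`. Stages always execute in dependency order; `"abc"` uses the
#'   adjusted rates when the `"adjust"` stage is also selected.
#' @param seed Seed for every stochastic stage (mandatory).
#' @param iterations Monte Carlo iterations for the CV null.
#' @param bootstrap_reps Parametric-bootstrap replicates.
#' @param fraction,min_cases Pared-mean settings.
#' @param criterion Hospital flag for the criterion-based benchmark.
#' @param covariates Case-mix covariates.
#' @param conf Confidence level.
#' @param ci_method Binomial interval method.
#' @return A list of class `act_run_config`.
#' @export
run_config <- function(out_dir,
                       patients_path = NULL, hospitals_path = NULL,
                       generator = NULL,
                       stages = "all",
                       seed = 1L,
                       iterations = 1000L,
                       bootstrap_reps = 1000L,
                       fraction = 0.10,
                       min_cases = 10L,
                       criterion = "cancer_centre",
                       covariates = act_covariates(),
                       conf = 0.95,
                       ci_method = "wilson") {
  from_files <- !is.null(patients_path) || !is.null(hospitals_path)
  if (from_files == !is.null(generator)) {
    abort("provide exactly one input source: cohort file paths or a generator config",
          class = "act_config_error")
  }
  all_stages <- c("summary", "rates", "mc-null", "adjust", "factors", "abc", "cbb")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) {
    abort(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")),
          class = "act_config_error")
  }
  structure(list(
    out_dir = out_dir, patients_path = patients_path,
    hospitals_path = hospitals_path, generator = generator,
    stages = intersect(all_stages, stages), seed = as.integer(seed),
    iterations = as.integer(iterations),
    bootstrap_reps = as.integer(bootstrap_reps), fraction = fraction,
    min_cases = as.integer(min_cases), criterion = criterion,
    covariates = covariates, conf = conf, ci_method = ci_method
  ), class = "act_run_config")
}

pipeline_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 69621 + k * 30011) %% 2147483647)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}

benchmark_as_list <- function(b) {
  list(
    method = b$method,
    selected_hospitals = b$selected$hospital_id,
    benchmark = list(n = b$benchmark_n, k = b$benchmark_k,
                     rate = b$benchmark_rate,
                     ci_low = b$benchmark_ci[1], ci_high = b$benchmark_ci[2]),
    nonbenchmark = list(n = b$nonbenchmark_n, k = b$nonbenchmark_k,
                        rate = b$nonbenchmark_rate,
                        ci_low = b$nonbenchmark_ci[1],
                        ci_high = b$nonbenchmark_ci[2]),
    comparison_rate = b$comparison_rate,
    comparison_basis = b$comparison_basis,
    shortfall_percent = b$shortfall_percent
  )
}

#' Per-level cohort summary table
#'
#' Counts and percentages of every categorical covariate level plus the
#' treated indicator — the classic cohort-characteristics table.
#'
#' @param cohort An `act_cohort` or patient-level data frame.
#' @return Tibble with columns `characteristic`, `level`, `n`, `percent`
#'   (integer percent, registry style).
#' @export
cohort_summary <- function(cohort) {
  patients <- cohort_patients(cohort)
  cols <- c(names(cohort_levels()), "treated")
  purrr::map_dfr(cols, function(col) {
    lv <- if (col == "treated") c("0", "1") else cohort_levels()[[col]]
    tab <- table(factor(as.character(patients[[col]]), levels = lv))
    tibble::tibble(
      characteristic = col, level = names(tab), n = as.integer(tab),
      percent = as.integer(round(100 * as.integer(tab) / nrow(patients)))
    )
  })
}

# Covariate distribution of benchmark vs non-benchmark patients.
benchmark_comparison_table <- function(patients, selected_ids) {
  grp <- ifelse(patients$hospital_id %in% selected_ids,
                "benchmark", "non_benchmark")
  purrr::map_dfr(names(cohort_levels()), function(col) {
    lv <- cohort_levels()[[col]]
    purrr::map_dfr(c("benchmark", "non_benchmark"), function(g) {
      sub <- patients[grp == g, ]
      tab <- table(factor(as.character(sub[[col]]), levels = lv))
      tibble::tibble(characteristic = col, level = names(tab), group = g,
                     n = as.integer(tab),
                     percent = as.integer(round(100 * as.integer(tab) /
                                                  max(1L, nrow(sub)))))
    })
  })
}

#' Run the full benchmarking pipeline
#'
#' Loads or generates the cohort, executes the selected stages in dependency
#' order, and writes every report artifact into the output directory:
#' cohort summary, hospital rate table and scatter data with provincial mean
#' and interval lines, the CV decomposition (JSON plus the simulated CV
#' draws), case-mix-adjusted rates, the system-factor table, pared-mean and
#' criterion-based benchmark results, ranked-rate data, and a manifest
#' recording the configuration, seed and package version. Re-running with an
#' identical configuration reproduces every artifact byte for byte.
#'
#' @param config An [run_config()].
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "act_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  results <- list()
  manifest <- list(
    package = "actbench",
    version = as.character(packageVersion("actbench")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages = config$stages,
    parameters = config[c("iterations", "bootstrap_reps", "fraction",
                          "min_cases", "criterion", "conf", "ci_method")],
    artifacts = list()
  )
  log_stage <- function(stage, rows_in, rows_out, files) {
    manifest$artifacts[[stage]] <<- list(rows_in = rows_in,
                                         rows_out = rows_out, files = files)
    message(sprintf("[%s] rows in: %d, rows out: %d -> %s",
                    stage, rows_in, rows_out, paste(files, collapse = ", ")))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            class = "act_stage_error", parent = e)
    })
  }

  if (!is.null(config$generator)) {
    sim <- run_stage("generate", generate_cohort(config$generator))
    coh <- sim$cohort
    write_cohort(coh, out("patients.csv"), out("hospitals.csv"))
    truth <- sim$truth
    write_json_artifact(list(
      intercept = truth$intercept,
      hospital_effects = truth$hospital_effects,
      covariate_log_odds = truth$covariate_log_odds,
      base_rate = truth$base_rate, hospital_sd = truth$hospital_sd
    ), out("truth.json"))
    log_stage("generate", 0L, nrow(coh$patients),
              c("patients.csv", "hospitals.csv", "truth.json"))
  } else {
    coh <- run_stage("load", read_cohort(config$patients_path,
                                         config$hospitals_path))
    log_stage("load", nrow(coh$patients), nrow(coh$patients), character())
  }
  results$cohort <- coh
  np <- nrow(coh$patients)

  if ("summary" %in% config$stages) {
    tab <- run_stage("summary", cohort_summary(coh))
    readr::write_csv(tab, out("cohort_summary.csv"))
    log_stage("summary", np, nrow(tab), "cohort_summary.csv")
    results$summary <- tab
  }

  rates <- NULL
  if (length(intersect(c("rates", "mc-null", "abc"), config$stages))) {
    rates <- run_stage("rates", hospital_rates(coh, conf = config$conf,
                                               ci_method = config$ci_method))
  }
  if ("rates" %in% config$stages) {
    readr::write_csv(tibble::as_tibble(rates), out("rates.csv"))
    pool <- pooled_rate(rates)
    write_json_artifact(pool, out("pooled_rate.json"))
    fig1a <- dplyr::mutate(tibble::as_tibble(rates),
                           provincial_rate = pool$rate,
                           provincial_ci_low = pool$ci_low,
                           provincial_ci_high = pool$ci_high)
    readr::write_tsv(fig1a, out("figure1a_hospital_rates.tsv"))
    log_stage("rates", np, nrow(rates),
              c("rates.csv", "pooled_rate.json", "figure1a_hospital_rates.tsv"))
    results$rates <- rates
  }

  if ("mc-null" %in% config$stages) {
    decomp <- run_stage("mc-null", decompose_variation(
      coh, iterations = config$iterations,
      seed = pipeline_seed(config$seed, 1L), conf = config$conf))
    write_json_artifact(glance(decomp), out("cv_decomposition.json"))
    readr::write_tsv(tidy(decomp), out("simulated_cvs.tsv"))
    log_stage("mc-null", nrow(rates), length(decomp$simulated_cvs),
              c("cv_decomposition.json", "simulated_cvs.tsv"))
    results$cv <- decomp
  }

  model <- NULL
  adjusted <- NULL
  if ("adjust" %in% config$stages) {
    model <- run_stage("adjust",
                       suppressWarnings(fit_outcome_model(coh, config$covariates)))
  }
  if ("adjust" %in% config$stages) {
    adjusted <- run_stage("adjust", adjusted_hospital_rates(
      coh, model, bootstrap_reps = config$bootstrap_reps,
      seed = pipeline_seed(config$seed, 2L), conf = config$conf))
    readr::write_csv(tibble::as_tibble(adjusted), out("adjusted_rates.csv"))
    readr::write_tsv(tibble::as_tibble(adjusted), out("figure1b_adjusted_rates.tsv"))
    write_json_artifact(tidy(model), out("outcome_model.json"))
    log_stage("adjust", nrow(model$data), nrow(adjusted),
              c("adjusted_rates.csv", "figure1b_adjusted_rates.tsv",
                "outcome_model.json"))
    results$adjusted <- adjusted
  }

  if ("factors" %in% config$stages) {
    flags <- intersect(c("teaching", "cancer_centre", "medonc_onsite"),
                       names(coh$hospitals))
    tab <- run_stage("factors", purrr::map_dfr(flags, function(f) {
      fe <- suppressWarnings(factor_effect(
        coh, f, covariates = config$covariates,
        boot_reps = config$bootstrap_reps,
        seed = pipeline_seed(config$seed, 3L), conf = config$conf))
      dplyr::mutate(tidy(fe),
                    percent = as.integer(round(100 * .data$rate)),
                    adj_percent = as.integer(round(100 * .data$adj_rate)),
                    rr_unadjusted = fe$rr_unadjusted,
                    rr_adjusted = fe$rr_adjusted)
    }))
    readr::write_csv(tab, out("factor_effects.csv"))
    log_stage("factors", np, nrow(tab), "factor_effects.csv")
    results$factors <- tab
  }

  if ("abc" %in% config$stages) {
    excl <- run_stage("abc", exclude_small_hospitals(rates, config$min_cases))
    abc <- run_stage("abc", pared_mean_benchmark(
      excl$rates, fraction = config$fraction, conf = config$conf,
      ci_method = config$ci_method))
    write_json_artifact(c(benchmark_as_list(abc), excl$report),
                        out("abc_benchmark.json"))
    ranked <- dplyr::arrange(tibble::as_tibble(excl$rates),
                             dplyr::desc(.data$rate), dplyr::desc(.data$n),
                             .data$hospital_id)
    ranked$rank <- seq_len(nrow(ranked))
    readr::write_tsv(ranked[c("rank", "hospital_id", "n", "k", "rate")],
                     out("figure2_ranked_rates.tsv"))
    comp <- benchmark_comparison_table(
      coh$patients[coh$patients$hospital_id %in% excl$rates$hospital_id, ],
      abc$selected$hospital_id)
    readr::write_csv(comp, out("benchmark_comparison.csv"))
    files <- c("abc_benchmark.json", "figure2_ranked_rates.tsv",
               "benchmark_comparison.csv")
    results$abc <- abc
    if (!is.null(adjusted)) {
      adj_eligible <- adjusted[adjusted$n >= config$min_cases, ]
      attr(adj_eligible, "draws") <- attr(adjusted, "draws")
      abc_adj <- run_stage("abc", pared_mean_benchmark(
        adj_eligible, fraction = config$fraction, rank_by = "adjusted",
        conf = config$conf))
      write_json_artifact(benchmark_as_list(abc_adj),
                          out("abc_adjusted_benchmark.json"))
      files <- c(files, "abc_adjusted_benchmark.json")
      results$abc_adjusted <- abc_adj
    }
    log_stage("abc", nrow(rates), nrow(excl$rates), files)
  }

  if ("cbb" %in% config$stages) {
    cbb <- run_stage("cbb", suppressWarnings(cbb_benchmark(
      coh, criterion = config$criterion, covariates = config$covariates,
      boot_reps = config$bootstrap_reps,
      seed = pipeline_seed(config$seed, 4L), conf = config$conf)))
    write_json_artifact(benchmark_as_list(cbb), out("cbb_benchmark.json"))
    log_stage("cbb", np, nrow(cbb$selected), "cbb_benchmark.json")
    results$cbb <- cbb
  }

  write_json_artifact(manifest, out("manifest.json"))
  invisible(results)
}
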