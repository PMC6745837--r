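#' Default covariate marginals for the synthetic cohort
#'
#' Marginal level probabilities for every categorical covariate, matching the
#' published characteristics of the Ontario stage III colon cancer cohort
#' (n = 2801): e.g. 66% treated overall, 31% aged 70-79, 81% Charlson 0,
#' 66% T3. Where the source table suppresses small cells to a range, the
#' midpoint consistent with the column total is used (node harvest
#' `<12` = 745, `unknown` = 5).
#'
#' @return Named list of named probability vectors, one per categorical
#'   covariate; each sums to 1.
#' @export
table1_marginals <- function() {
  n <- 2801
  list(
    age_group    = c("20-49" = 207, "50-59" = 437, "60-69" = 727,
                     "70-79" = 872, "80+" = 558) / n,
    sex          = c("F" = 1339, "M" = 1462) / n,
    ses_quintile = c("1" = 595, "2" = 648, "3" = 590, "4" = 509, "5" = 453,
                     "unknown" = 6) / n,
    charlson     = c("0" = 2267, "1" = 313, "2+" = 221) / n,
    t_stage      = c("T<=1" = 43, "T2" = 180, "T3" = 1854, "T4" = 724) / n,
    n_stage      = c("N1" = 1663, "N2" = 1138) / n,
    grade        = c("well-moderate" = 2141, "poor" = 610, "unstated" = 50) / n,
    lvi          = c("no" = 1209, "yes" = 1378, "NA" = 214) / n,
    node_harvest = c(">=12" = 2051, "<12" = 745, "unknown" = 5) / n
  )
}

#' Default covariate effects on treatment (log-odds scale)
#'
#' Older patients and patients with more comorbidity are substantially less
#' likely to start adjuvant chemotherapy; all other covariates carry no
#' effect by default. The age gradient runs from 0 (ages 20-49, reference)
#' to -3 log-odds (80+, odds ratio ~0.05), and the Charlson gradient from 0
#' to -0.8 (score 2+), magnitudes typical of population-based adjuvant
#' chemotherapy studies in the elderly.
#'
#' @return Named list mapping covariate name to a named vector of per-level
#'   log-odds offsets (reference level 0). The special entry
#'   `length_of_stay` is a per-day slope applied to `(days - 8)`.
#' @export
default_log_odds <- function() {
  list(
    age_group = c("20-49" = 0, "50-59" = -0.2, "60-69" = -0.6,
                  "70-79" = -1.5, "80+" = -3.0),
    charlson  = c("0" = 0, "1" = -0.4, "2+" = -0.8)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the published study: 72 hospitals, 2801 patients, overall
#' treatment probability 0.66, covariate marginals from [table1_marginals()],
#' age and comorbidity effects from [default_log_odds()], and no systematic
#' hospital effect (`hospital_sd = 0`, the pure-chance null under which every
#' hospital shares the provincial treatment probability).
#'
#' @param n_hospitals Number of hospitals (default 72).
#' @param n_patients Total patients (default 2801).
#' @param base_rate Marginal treatment probability the intercept is
#'   calibrated to (default 0.66).
#' @param hospital_size_profile `"study-like"` (heavy-tailed lognormal volume
#'   profile, so a realistic handful of hospitals fall under 10 cases),
#'   `"uniform"`, or a numeric vector of `n_hospitals` custom weights.
#' @param size_sdlog Lognormal sigma of the study-like volume profile
#'   (default 1.1).
#' @param n_small_hospitals Optionally force exactly this many hospitals
#'   below 10 cases (default `NULL`: whatever the profile yields).
#' @param covariate_marginals Named list of level probabilities per
#'   categorical covariate; each must sum to 1.
#' @param covariate_log_odds Named list of per-level log-odds effects on
#'   treatment (see [default_log_odds()]).
#' @param hospital_sd Standard deviation of hospital random intercepts on the
#'   log-odds scale; 0 is the binomial null.
#' @param case_mix_skew_covariate Optional categorical covariate whose level
#'   distribution varies systematically between hospitals (e.g.
#'   `"age_group"`: some hospitals see older patients). `NULL` (default)
#'   keeps covariates identically distributed at every hospital.
#' @param case_mix_skew_sd Standard deviation of the per-hospital exponential
#'   tilt along the ordered levels of the skewed covariate (0 = no skew).
#'   Each hospital draws a tilt \eqn{s_h \sim N(0, sd)} and samples level
#'   \eqn{j} with probability proportional to \eqn{m_j e^{s_h (j - \bar j)}}.
#' @param flag_probs Probabilities that a hospital is a teaching hospital, a
#'   comprehensive cancer centre, or has medical oncology on site (defaults
#'   14/72, 13/72, 32/72, the published hospital counts). Cancer centres are
#'   always a subset of hospitals with on-site medical oncology.
#' @param los_meanlog,los_sdlog Lognormal parameters of length of stay in
#'   days (defaults give median 8 days).
#' @param seed Master seed; stage-specific substreams (sizes, flags,
#'   covariates, hospital intercepts, outcomes) are derived from it so that
#'   changing one stage does not perturb the others.
#' @return A list of class `act_generator_config`.
#' @export
generator_config <- function(n_hospitals = 72,
                             n_patients = 2801,
                             base_rate = 0.66,
                             hospital_size_profile = "study-like",
                             size_sdlog = 1.1,
                             n_small_hospitals = NULL,
                             covariate_marginals = table1_marginals(),
                             covariate_log_odds = default_log_odds(),
                             hospital_sd = 0,
                             case_mix_skew_covariate = NULL,
                             case_mix_skew_sd = 0,
                             flag_probs = c(teaching = 14 / 72,
                                            cancer_centre = 13 / 72,
                                            medonc_onsite = 32 / 72),
                             los_meanlog = log(8),
                             los_sdlog = 0.45,
                             seed = 1L) {
  covariate_marginals <- utils::modifyList(table1_marginals(),
                                           as.list(covariate_marginals))
  cfg <- list(
    n_hospitals = as.integer(n_hospitals), n_patients = as.integer(n_patients),
    base_rate = base_rate, hospital_size_profile = hospital_size_profile,
    size_sdlog = size_sdlog, n_small_hospitals = n_small_hospitals,
    covariate_marginals = covariate_marginals,
    covariate_log_odds = covariate_log_odds, hospital_sd = hospital_sd,
    case_mix_skew_covariate = case_mix_skew_covariate,
    case_mix_skew_sd = case_mix_skew_sd,
    flag_probs = flag_probs, los_meanlog = los_meanlog,
    los_sdlog = los_sdlog, seed = as.integer(seed)
  )
  class(cfg) <- "act_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_hospitals < 1L || cfg$n_patients < 1L) {
    abort("n_hospitals and n_patients must be positive", class = "act_config_error")
  }
  if (cfg$n_hospitals > cfg$n_patients) {
    abort("infeasible size profile: n_hospitals exceeds n_patients",
          class = "act_config_error")
  }
  if (cfg$base_rate < 0 || cfg$base_rate > 1) {
    abort("base_rate must be a probability", class = "act_config_error")
  }
  if (cfg$hospital_sd < 0) {
    abort("hospital_sd must be non-negative", class = "act_config_error")
  }
  lv <- cohort_levels()
  for (col in names(cfg$covariate_marginals)) {
    m <- cfg$covariate_marginals[[col]]
    if (!col %in% names(lv)) {
      abort(sprintf("unknown covariate in marginals: %s", col),
            class = "act_config_error")
    }
    if (!setequal(names(m), lv[[col]])) {
      abort(sprintf("marginals for %s must name exactly levels {%s}",
                    col, paste(lv[[col]], collapse = ", ")),
            class = "act_config_error")
    }
    if (any(m < 0) || abs(sum(m) - 1) > 1e-6) {
      abort(sprintf("marginals for %s must be probabilities summing to 1", col),
            class = "act_config_error")
    }
  }
  for (col in names(cfg$covariate_log_odds)) {
    if (!col %in% c(names(lv), "length_of_stay")) {
      abort(sprintf("unknown covariate in covariate_log_odds: %s", col),
            class = "act_config_error")
    }
  }
  if (!is.null(cfg$case_mix_skew_covariate) &&
      !cfg$case_mix_skew_covariate %in% names(lv)) {
    abort("case_mix_skew_covariate must name a categorical covariate",
          class = "act_config_error")
  }
  if (cfg$case_mix_skew_sd < 0) {
    abort("case_mix_skew_sd must be non-negative", class = "act_config_error")
  }
  if (is.numeric(cfg$hospital_size_profile) &&
      length(cfg$hospital_size_profile) != cfg$n_hospitals) {
    abort("custom size weights must have length n_hospitals",
          class = "act_config_error")
  }
  invisible(cfg)
}

# Deterministic per-stage substream seed derived from the master seed.
substream_seed <- function(seed, stage) {
  k <- match(stage, c("sizes", "flags", "covariates", "intercepts", "outcomes"))
  s <- ((as.numeric(seed) %% 2147483647) * 48271) %% 2147483647
  as.integer((s + k * 104729) %% 2147483647)
}

# Largest-remainder apportionment of n into positive integers by weight.
apportion_sizes <- function(weights, n) {
  stopifnot(all(weights > 0), n >= length(weights))
  share <- weights / sum(weights) * n
  sizes <- floor(share)
  rem <- n - sum(sizes)
  if (rem > 0) {
    bump <- order(share - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[bump] <- sizes[bump] + 1
  }
  while (any(sizes == 0)) {
    i <- which.max(sizes)
    j <- which(sizes == 0)[1]
    sizes[i] <- sizes[i] - 1
    sizes[j] <- 1
  }
  as.integer(sizes)
}

draw_hospital_sizes <- function(cfg) {
  profile <- cfg$hospital_size_profile
  h <- cfg$n_hospitals
  if (is.numeric(profile)) {
    w <- profile
  } else if (identical(profile, "uniform")) {
    w <- rep(1, h)
  } else if (identical(profile, "study-like")) {
    w <- rlnorm(h, meanlog = 0, sdlog = cfg$size_sdlog)
  } else {
    abort("hospital_size_profile must be 'study-like', 'uniform', or numeric weights",
          class = "act_config_error")
  }
  sizes <- apportion_sizes(w, cfg$n_patients)
  if (!is.null(cfg$n_small_hospitals)) {
    sizes <- force_small_count(sizes, cfg$n_small_hospitals)
  }
  sizes
}

# Adjust an apportionment so exactly `target` hospitals have < 10 cases,
# conserving the total.
force_small_count <- function(sizes, target) {
  target <- as.integer(target)
  if (target > length(sizes)) {
    abort("n_small_hospitals exceeds n_hospitals", class = "act_config_error")
  }
  repeat {
    small <- sizes < 10
    if (sum(small) == target) break
    if (sum(small) < target) {
      # shrink the smallest non-small hospital into the small range
      j <- which(!small)[which.min(sizes[!small])]
      new_size <- sample(4:9, 1)
      surplus <- sizes[j] - new_size
      sizes[j] <- new_size
      i <- which.max(sizes)
      sizes[i] <- sizes[i] + surplus
    } else {
      # grow the largest small hospital to 10, funded by the largest hospital
      j <- which(small)[which.max(sizes[small])]
      need <- 10 - sizes[j]
      i <- which.max(sizes)
      if (sizes[i] - need < 10) {
        abort("cannot satisfy n_small_hospitals with this total", class = "act_config_error")
      }
      sizes[i] <- sizes[i] - need
      sizes[j] <- 10L
    }
  }
  as.integer(sizes)
}

draw_hospital_flags <- function(cfg, hospital_id) {
  h <- length(hospital_id)
  n_medonc <- min(h, round(cfg$flag_probs[["medonc_onsite"]] * h))
  n_cc <- min(n_medonc, round(cfg$flag_probs[["cancer_centre"]] * h))
  n_teach <- min(h, round(cfg$flag_probs[["teaching"]] * h))
  medonc <- sample(seq_len(h), n_medonc)
  cc <- if (n_cc > 0) sample(medonc, n_cc) else integer()
  teach <- sample(seq_len(h), n_teach)
  tibble::tibble(
    hospital_id = hospital_id,
    teaching = as.integer(seq_len(h) %in% teach),
    cancer_centre = as.integer(seq_len(h) %in% cc),
    medonc_onsite = as.integer(seq_len(h) %in% medonc)
  )
}

# Per-patient covariate contribution to the linear predictor.
covariate_eta <- function(patients, covariate_log_odds) {
  eta <- numeric(nrow(patients))
  for (col in names(covariate_log_odds)) {
    eff <- covariate_log_odds[[col]]
    if (identical(col, "length_of_stay")) {
      eta <- eta + eff * (patients$length_of_stay - 8)
    } else {
      full <- setNames(numeric(length(cohort_levels()[[col]])),
                       cohort_levels()[[col]])
      full[names(eff)] <- eff
      eta <- eta + unname(full[as.character(patients[[col]])])
    }
  }
  eta
}

# Discrete distribution of the covariate linear-predictor offset implied by
# independent categorical marginals (exact convolution).
eta_distribution <- function(cfg) {
  vals <- 0
  probs <- 1
  for (col in names(cfg$covariate_log_odds)) {
    eff <- cfg$covariate_log_odds[[col]]
    if (identical(col, "length_of_stay")) {
      if (eff == 0) next
      d <- 0:ceiling(exp(cfg$los_meanlog + 8 * cfg$los_sdlog))
      pd <- plnorm(d + 0.5, cfg$los_meanlog, cfg$los_sdlog) -
        plnorm(pmax(d - 0.5, 0), cfg$los_meanlog, cfg$los_sdlog)
      pd[1] <- plnorm(0.5, cfg$los_meanlog, cfg$los_sdlog)
      pd <- pd / sum(pd)
      v2 <- eff * (d - 8)
    } else {
      m <- cfg$covariate_marginals[[col]]
      if (is.null(m)) {
        abort(sprintf("covariate_log_odds names %s but no marginals are given", col),
              class = "act_config_error")
      }
      full <- setNames(numeric(length(m)), names(m))
      full[names(eff)] <- eff
      v2 <- unname(full[names(m)])
      pd <- unname(m)
    }
    grid_v <- outer(vals, v2, `+`)
    grid_p <- outer(probs, pd, `*`)
    key <- factor(round(as.vector(grid_v), 12))
    probs <- as.vector(tapply(as.vector(grid_p), key, sum))
    vals <- as.numeric(levels(key))
  }
  list(values = vals, probs = probs)
}

#' Calibrate the logistic intercept to a target marginal treatment rate
#'
#' Finds the intercept \eqn{\beta_0} such that the model-implied marginal
#' probability of treatment, averaged exactly over the configured covariate
#' distribution (and over the hospital random-intercept distribution when
#' `hospital_sd > 0`), equals `base_rate`. The marginal mean of a logistic
#' model is strictly increasing in the intercept, so monotone root-finding
#' (Brent) converges to machine tolerance.
#'
#' @param config An [generator_config()] object.
#' @return The intercept on the log-odds scale.
#' @export
#' @examples
#' cfg <- generator_config(covariate_log_odds = list())
#' calibrate_intercept(cfg)  # logit(0.66)
calibrate_intercept <- function(config) {
  dist <- eta_distribution(config)
  sdu <- config$hospital_sd
  if (config$base_rate <= 0) return(-Inf)
  if (config$base_rate >= 1) return(Inf)
  marginal_mean <- function(b0) {
    if (sdu == 0) {
      sum(dist$probs * plogis(b0 + dist$values))
    } else {
      sum(dist$probs * vapply(dist$values, function(v) {
        integrate(function(u) plogis(b0 + v + u) * dnorm(u, 0, sdu),
                  -Inf, Inf, rel.tol = 1e-10)$value
      }, numeric(1)))
    }
  }
  uniroot(function(b0) marginal_mean(b0) - config$base_rate,
          interval = c(-40, 40), tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' Draws hospital volumes from the configured size profile, hospital system
#' flags, independent categorical covariates from the configured marginals,
#' hospital random intercepts, and treatment indicators from the logistic
#' model \eqn{\mathrm{logit}(p) = \beta_0 + x'\beta + u_h} with \eqn{\beta_0}
#' from [calibrate_intercept()]. Identical configuration and seed give an
#' identical cohort.
#'
#' @param config An [generator_config()] object.
#' @return A list with elements `cohort` (an `act_cohort`) and `truth` (class
#'   `act_truth`: the calibrated intercept, the per-hospital random
#'   intercepts and realized sizes, and the covariate effects used —
#'   everything needed for parameter-recovery checks).
#' @export
#' @examples
#' sim <- generate_cohort(generator_config(n_hospitals = 5, n_patients = 200))
#' sim$cohort
generate_cohort <- function(config) {
  validate_generator_config(config)
  h <- config$n_hospitals
  n <- config$n_patients
  hospital_id <- sprintf("H%0*d", max(2L, nchar(h)), seq_len(h))

  set.seed(substream_seed(config$seed, "sizes"))
  sizes <- draw_hospital_sizes(config)

  set.seed(substream_seed(config$seed, "flags"))
  hospitals <- draw_hospital_flags(config, hospital_id)

  set.seed(substream_seed(config$seed, "covariates"))
  hosp_of_patient <- rep(seq_len(h), times = sizes)
  patients <- tibble::tibble(
    patient_id = sprintf("P%0*d", max(4L, nchar(n)), seq_len(n)),
    hospital_id = hospital_id[hosp_of_patient],
    treated = 0L
  )
  skew_col <- config$case_mix_skew_covariate
  skew <- if (!is.null(skew_col) && config$case_mix_skew_sd > 0) {
    rnorm(h, 0, config$case_mix_skew_sd)
  } else {
    rep(0, h)
  }
  for (col in names(config$covariate_marginals)) {
    m <- config$covariate_marginals[[col]]
    if (identical(col, skew_col) && any(skew != 0)) {
      j <- seq_along(m) - mean(seq_along(m))
      patients[[col]] <- unlist(lapply(seq_len(h), function(hh) {
        if (sizes[hh] == 0) return(character())
        ph <- m * exp(skew[hh] * j)
        sample(names(m), sizes[hh], replace = TRUE, prob = ph / sum(ph))
      }))
    } else {
      patients[[col]] <- sample(names(m), n, replace = TRUE, prob = m)
    }
  }
  patients$length_of_stay <- as.integer(pmax(0, round(
    rlnorm(n, config$los_meanlog, config$los_sdlog))))

  set.seed(substream_seed(config$seed, "intercepts"))
  u <- rnorm(h, 0, config$hospital_sd)

  intercept <- calibrate_intercept(config)
  eta <- intercept + covariate_eta(patients, config$covariate_log_odds) +
    u[hosp_of_patient]

  set.seed(substream_seed(config$seed, "outcomes"))
  patients$treated <- rbinom(n, 1L, plogis(eta))
  patients <- patients[patient_columns()]

  truth <- structure(list(
    intercept = intercept,
    hospital_effects = tibble::tibble(hospital_id = hospital_id,
                                      size = sizes, u = u,
                                      case_mix_skew = skew),
    covariate_log_odds = config$covariate_log_odds,
    base_rate = config$base_rate,
    hospital_sd = config$hospital_sd,
    seed = config$seed
  ), class = "act_truth")

  list(cohort = cohort(patients, hospitals), truth = truth)
}
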