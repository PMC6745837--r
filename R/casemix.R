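#' Default case-mix covariate set
#'
#' The patient- and disease-related covariates entering every adjusted model:
#' age group, sex, socioeconomic quintile, Charlson comorbidity, length of
#' stay (days, numeric), T stage, N stage, lymphovascular invasion, and
#' histological grade.
#'
#' @return Character vector of covariate names.
#' @export
act_covariates <- function() {
  c("age_group", "sex", "ses_quintile", "charlson", "length_of_stay",
    "t_stage", "n_stage", "lvi", "grade")
}

# Reference levels used for treatment-effect coding: youngest age group,
# female, lowest SES quintile, Charlson 0, T3 (the modal stage), N1,
# well-moderate grade, no LVI, adequate node harvest.
reference_levels <- function() {
  c(age_group = "20-49", sex = "F", ses_quintile = "1", charlson = "0",
    t_stage = "T3", n_stage = "N1", grade = "well-moderate", lvi = "no",
    node_harvest = ">=12")
}

# Encode the analysis data set: factors with documented reference levels,
# numeric length of stay, hospital id retained for grouping. SES "unknown"
# rows (a handful in the emulated study) are dropped with a warning by
# default, or kept as an own category.
prepare_model_data <- function(cohort, covariates,
                               ses_unknown = c("drop", "category"),
                               extra = NULL) {
  ses_unknown <- match.arg(ses_unknown)
  patients <- cohort_patients(cohort)
  if (!is.null(extra)) {
    patients <- dplyr::left_join(patients, extra, by = "hospital_id")
  }
  bad <- setdiff(covariates, c(names(cohort_levels()), "length_of_stay"))
  if (length(bad)) abort(sprintf("unknown covariate(s): %s", paste(bad, collapse = ", ")))

  n_dropped <- 0L
  if ("ses_quintile" %in% covariates && ses_unknown == "drop") {
    drop <- patients$ses_quintile == "unknown"
    n_dropped <- sum(drop)
    if (n_dropped > 0) {
      warn(sprintf("dropping %d patient(s) with unknown SES; use ses_unknown = 'category' to keep them",
                   n_dropped))
      patients <- patients[!drop, ]
    }
  }
  lv <- cohort_levels()
  refs <- reference_levels()
  for (col in intersect(covariates, names(lv))) {
    f <- factor(patients[[col]], levels = lv[[col]])
    f <- droplevels(f)
    if (refs[[col]] %in% levels(f)) f <- stats::relevel(f, ref = refs[[col]])
    patients[[col]] <- f
  }
  if ("length_of_stay" %in% covariates) {
    patients$length_of_stay <- as.numeric(patients$length_of_stay)
  }
  attr(patients, "n_dropped_ses") <- n_dropped
  patients
}

# Error on any covariate level that perfectly predicts the outcome (complete
# separation would leave the MLE unbounded).
check_separation <- function(data, covariates) {
  for (col in covariates) {
    if (!is.factor(data[[col]])) next
    tab <- table(data[[col]], data$treated)
    if (ncol(tab) < 2) {
      abort("model requires at least one event and one non-event")
    }
    sep <- rowSums(tab) > 0 & (tab[, 1] == 0 | tab[, 2] == 0)
    if (any(sep)) {
      abort(sprintf(
        "complete separation: level '%s' of %s perfectly predicts treatment",
        names(which(sep))[1], col), class = "act_separation_error")
    }
  }
  invisible(data)
}

#' Fit the multivariable logistic outcome model
#'
#' Maximum-likelihood logistic regression of the treatment indicator on the
#' case-mix covariates (reference-coded; see the model print for reference
#' levels). Complete separation and degenerate outcomes are detected before
#' fitting and raised as errors naming the offending covariate.
#'
#' @param cohort An `act_cohort` (or patient-level data frame containing the
#'   covariate columns plus `treated` and `hospital_id`).
#' @param covariates Covariate names (default [act_covariates()]).
#' @param ses_unknown `"drop"` rows with unknown SES (default, with a
#'   warning) or keep `"category"`.
#' @return An object of class `act_outcome_model`: the `glm` fit, the
#'   analysis data (with `hospital_id`), covariate specification, reference
#'   levels and convergence flag. Supports [tidy()] and [glance()].
#' @export
fit_outcome_model <- function(cohort, covariates = act_covariates(),
                              ses_unknown = c("drop", "category")) {
  data <- prepare_model_data(cohort, covariates, ses_unknown)
  if (length(unique(data$treated)) < 2) {
    abort("model requires at least one event and one non-event")
  }
  check_separation(data, covariates)
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  fit <- glm(as.formula(paste("treated ~", rhs)), family = binomial(),
             data = data)
  if (!fit$converged) abort("logistic model did not converge")
  structure(list(
    fit = fit,
    covariates = covariates,
    reference_levels = reference_levels()[intersect(names(reference_levels()), covariates)],
    data = data,
    n_dropped_ses = attr(data, "n_dropped_ses"),
    converged = fit$converged
  ), class = "act_outcome_model")
}

#' @export
print.act_outcome_model <- function(x, ...) {
  cat(sprintf("<act_outcome_model> logistic fit on %d patients, %d terms\n",
              nrow(x$data), length(coef(x$fit))))
  if (length(x$reference_levels)) {
    cat("  reference levels:",
        paste(names(x$reference_levels), x$reference_levels, sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname fit_outcome_model
#' @param x,object An `act_outcome_model`.
#' @param conf Confidence level for Wald intervals.
#' @param ... Unused.
#' @method tidy act_outcome_model
#' @export
tidy.act_outcome_model <- function(x, conf = 0.95, ...) {
  s <- summary(x$fit)$coefficients
  z <- qnorm(1 - (1 - conf) / 2)
  tibble::tibble(
    term = rownames(s), estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4],
    conf.low = s[, 1] - z * s[, 2], conf.high = s[, 1] + z * s[, 2]
  )
}

#' @rdname fit_outcome_model
#' @method glance act_outcome_model
#' @export
glance.act_outcome_model <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$data), n_dropped_ses = x$n_dropped_ses,
    null.deviance = x$fit$null.deviance, deviance = x$fit$deviance,
    AIC = stats::AIC(x$fit), converged = x$converged
  )
}

#' Case-mix-adjusted hospital rates by indirect standardization
#'
#' For each hospital the expected rate is the mean model-predicted treatment
#' probability over that hospital's own patients, and the adjusted rate is
#' the observed-to-expected ratio rescaled to the pooled rate,
#' \eqn{(O/E) \times \bar p}. Confidence intervals come from a parametric
#' bootstrap in which each replicate (i) redraws the model coefficients from
#' their asymptotic normal distribution and (ii) redraws every patient's
#' outcome from the implied probabilities, recomputing the adjusted rate;
#' intervals are percentile-based.
#'
#' @param cohort An `act_cohort` (used for its patient table; the model's
#'   analysis rows are what is standardized).
#' @param model An [fit_outcome_model()] object on the same covariate
#'   specification.
#' @param bootstrap_reps Bootstrap replicates (default 1000; 0 skips the
#'   intervals).
#' @param seed Optional seed.
#' @param conf Confidence level.
#' @return A tibble of class `act_adjusted_rates`: `hospital_id`, `n`, `k`,
#'   `observed`, `expected`, `adjusted`, `ci_low`, `ci_high`; the pooled rate
#'   as attribute `pooled` and the bootstrap draws (replicates x hospitals)
#'   as attribute `draws`.
#' @export
adjusted_hospital_rates <- function(cohort, model, bootstrap_reps = 1000L,
                                    seed = NULL, conf = 0.95) {
  stopifnot(inherits(model, "act_outcome_model"))
  data <- model$data
  p_hat <- fitted(model$fit)
  hosp <- factor(data$hospital_id)
  n_h <- as.vector(table(hosp))
  k_h <- as.vector(rowsum(data$treated, hosp))
  obs <- k_h / n_h
  expd <- as.vector(rowsum(p_hat, hosp)) / n_h
  if (any(expd == 0)) abort("hospital expected rate 0; cannot standardize")
  pool <- mean(data$treated)
  adjusted <- obs / expd * pool

  out <- tibble::tibble(
    hospital_id = levels(hosp), n = n_h, k = as.integer(k_h),
    observed = obs, expected = expd, adjusted = adjusted,
    ci_low = NA_real_, ci_high = NA_real_
  )
  draws <- NULL
  if (bootstrap_reps > 0) {
    if (!is.null(seed)) set.seed(seed)
    X <- model.matrix(model$fit)
    B <- MASS::mvrnorm(bootstrap_reps, coef(model$fit), vcov(model$fit))
    P <- plogis(X %*% t(B))                       # patients x reps
    Eh <- rowsum(P, hosp) / n_h                   # hospitals x reps
    # outcome probabilities implied for each hospital: model probabilities
    # rescaled by the hospital's observed/expected ratio, so the redrawn
    # outcomes are centred on each hospital's own standardized level
    ratio <- obs / Eh                             # hospitals x reps
    Pstar <- pmin(1, P * ratio[as.integer(hosp), , drop = FALSE])
    Y <- (matrix(runif(length(P)), nrow(P)) < Pstar) * 1
    Oh <- rowsum(Y, hosp) / n_h
    pool_r <- colSums(Y) / sum(n_h)
    Adj <- sweep(Oh / Eh, 2, pool_r, `*`)
    a <- (1 - conf) / 2
    qs <- apply(Adj, 1, quantile, probs = c(a, 1 - a), na.rm = TRUE)
    out$ci_low <- qs[1, ]
    out$ci_high <- qs[2, ]
    draws <- t(Adj)
    colnames(draws) <- levels(hosp)
  }
  attr(out, "pooled") <- list(n = sum(n_h), k = sum(k_h), rate = pool,
                              ci_low = binomial_ci(sum(k_h), sum(n_h), conf)$ci_low,
                              ci_high = binomial_ci(sum(k_h), sum(n_h), conf)$ci_high,
                              conf = conf, ci_method = "wilson")
  attr(out, "draws") <- draws
  class(out) <- c("act_adjusted_rates", class(out))
  out
}

#' Effect of a hospital system-level factor on treatment
#'
#' Unadjusted rates and relative risk across the two levels of a binary
#' hospital attribute, and case-mix-adjusted rates and relative risk by
#' marginal standardization: a logistic model containing the factor plus the
#' covariates is fitted, then the average predicted probability over the
#' *entire* cohort is computed with the factor set to each level in turn; the
#' adjusted RR is the ratio of these standardized rates. The unadjusted RR
#' interval is the Katz log interval; adjusted intervals come from a
#' parametric bootstrap of the model coefficients.
#'
#' @param cohort An `act_cohort` (the hospital table supplies the factor).
#' @param factor One of `"teaching"`, `"cancer_centre"`, `"medonc_onsite"`
#'   (or any binary column of the hospital table).
#' @param covariates Case-mix covariates (default [act_covariates()]; empty
#'   vector gives purely unadjusted standardization, where adjusted and
#'   unadjusted RR coincide exactly).
#' @param boot_reps Bootstrap replicates (default 1000; 0 skips intervals).
#' @param seed Optional seed.
#' @param conf Confidence level.
#' @param ses_unknown Passed to the data preparation (see
#'   [fit_outcome_model()]).
#' @return An object of class `act_factor_effect`; [tidy()] gives the
#'   per-level table, [glance()] the RRs.
#' @export
factor_effect <- function(cohort, factor, covariates = act_covariates(),
                          boot_reps = 1000L, seed = NULL, conf = 0.95,
                          ses_unknown = c("drop", "category")) {
  stopifnot(inherits(cohort, "act_cohort"))
  if (!factor %in% names(cohort$hospitals)) {
    abort(sprintf("factor '%s' is not a hospital attribute", factor))
  }
  flags <- cohort$hospitals[, c("hospital_id", factor)]
  data <- prepare_model_data(cohort, covariates, ses_unknown, extra = flags)
  data$.factor <- factor(as.character(data[[factor]]), levels = c("0", "1"))
  if (length(unique(data$.factor)) < 2) {
    abort(sprintf("factor '%s' is constant across the cohort", factor))
  }
  if (length(unique(data$treated)) < 2) {
    abort("model requires at least one event and one non-event")
  }
  check_separation(data, covariates)

  counts <- data %>%
    dplyr::group_by(level = .data$.factor) %>%
    dplyr::summarise(n = dplyr::n(), k = sum(.data$treated), .groups = "drop") %>%
    dplyr::mutate(rate = .data$k / .data$n)
  r0 <- counts$rate[counts$level == "0"]
  r1 <- counts$rate[counts$level == "1"]
  rr_unadj <- r1 / r0
  z <- qnorm(1 - (1 - conf) / 2)
  se_log <- sqrt(1 / counts$k[counts$level == "1"] - 1 / counts$n[counts$level == "1"] +
                 1 / counts$k[counts$level == "0"] - 1 / counts$n[counts$level == "0"])
  rr_unadj_ci <- exp(log(rr_unadj) + c(-z, z) * se_log)

  rhs <- paste(c(".factor", covariates), collapse = " + ")
  fit <- glm(as.formula(paste("treated ~", rhs)), family = binomial(), data = data)
  if (!fit$converged) abort("logistic model did not converge")
  tt <- stats::delete.response(terms(fit))
  X_at <- function(lev) {
    d <- data
    d$.factor <- factor(lev, levels = c("0", "1"))
    model.matrix(tt, d)
  }
  X0 <- X_at("0"); X1 <- X_at("1")
  beta <- coef(fit)
  g0 <- mean(plogis(drop(X0 %*% beta)))
  g1 <- mean(plogis(drop(X1 %*% beta)))
  rr_adj <- g1 / g0

  g_ci <- matrix(NA_real_, 2, 2)
  rr_adj_ci <- c(NA_real_, NA_real_)
  if (boot_reps > 0) {
    if (!is.null(seed)) set.seed(seed)
    B <- MASS::mvrnorm(boot_reps, beta, vcov(fit))
    G0 <- colMeans(plogis(X0 %*% t(B)))
    G1 <- colMeans(plogis(X1 %*% t(B)))
    a <- (1 - conf) / 2
    g_ci <- cbind(quantile(G0, c(a, 1 - a)), quantile(G1, c(a, 1 - a)))
    rr_adj_ci <- unname(quantile(G1 / G0, c(a, 1 - a)))
  }

  levels_tbl <- counts %>%
    dplyr::mutate(adj_rate = c(g0, g1)[match(.data$level, c("0", "1"))],
                  adj_ci_low = g_ci[1, match(.data$level, c("0", "1"))],
                  adj_ci_high = g_ci[2, match(.data$level, c("0", "1"))])

  structure(list(
    factor = factor, levels = levels_tbl,
    rr_unadjusted = rr_unadj, rr_unadjusted_ci = rr_unadj_ci,
    rr_adjusted = rr_adj, rr_adjusted_ci = rr_adj_ci,
    fit = fit, conf = conf, covariates = covariates
  ), class = "act_factor_effect")
}

#' @export
print.act_factor_effect <- function(x, ...) {
  cat(sprintf("<act_factor_effect> %s\n", x$factor))
  print(x$levels)
  cat(sprintf("  unadjusted RR %.3f (%.3f-%.3f); adjusted RR %.3f (%.3f-%.3f)\n",
              x$rr_unadjusted, x$rr_unadjusted_ci[1], x$rr_unadjusted_ci[2],
              x$rr_adjusted, x$rr_adjusted_ci[1], x$rr_adjusted_ci[2]))
  invisible(x)
}

#' @rdname factor_effect
#' @param x,object An `act_factor_effect`.
#' @param ... Unused.
#' @method tidy act_factor_effect
#' @export
tidy.act_factor_effect <- function(x, ...) {
  dplyr::mutate(x$levels, factor = x$factor, .before = 1)
}

#' @rdname factor_effect
#' @method glance act_factor_effect
#' @export
glance.act_factor_effect <- function(x, ...) {
  tibble::tibble(
    factor = x$factor,
    rr_unadjusted = x$rr_unadjusted,
    rr_unadjusted_low = x$rr_unadjusted_ci[1],
    rr_unadjusted_high = x$rr_unadjusted_ci[2],
    rr_adjusted = x$rr_adjusted,
    rr_adjusted_low = x$rr_adjusted_ci[1],
    rr_adjusted_high = x$rr_adjusted_ci[2]
  )
}

#' Between-hospital intraclass correlation from a multilevel model
#'
#' Fits a random-intercept logistic model (hospital intercepts) on the
#' case-mix covariates and reports the hospital variance \eqn{\sigma^2_u}
#' and the latent-scale intraclass correlation
#' \eqn{\sigma^2_u / (\sigma^2_u + \pi^2/3)}, the share of latent outcome
#' variation attributable to between-hospital differences.
#'
#' @inheritParams fit_outcome_model
#' @return An object of class `act_icc`: `sigma2_u`, `icc`, the `glmer` fit
#'   and any optimizer messages. Non-convergence of the optimizer is an
#'   error carrying the diagnostics.
#' @export
multilevel_icc <- function(cohort, covariates = act_covariates(),
                           ses_unknown = c("drop", "category")) {
  data <- prepare_model_data(cohort, covariates, ses_unknown)
  if (length(unique(data$hospital_id)) < 2) abort("need at least 2 hospitals")
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  fml <- as.formula(paste("treated ~", rhs, "+ (1 | hospital_id)"))
  fit <- lme4::glmer(fml, data = data, family = binomial())
  conv <- fit@optinfo$conv
  if (!is.null(conv$opt) && conv$opt != 0) {
    abort(c("random-intercept model did not converge",
            unlist(conv$lme4$messages)))
  }
  sigma2 <- as.numeric(lme4::VarCorr(fit)$hospital_id[1, 1])
  structure(list(
    sigma2_u = sigma2,
    icc = sigma2 / (sigma2 + pi^2 / 3),
    fit = fit,
    messages = unlist(conv$lme4$messages)
  ), class = "act_icc")
}

#' @export
print.act_icc <- function(x, ...) {
  cat(sprintf("<act_icc> hospital variance %.4f; latent-scale ICC %.4f\n",
              x$sigma2_u, x$icc))
  invisible(x)
}

#' @rdname multilevel_icc
#' @param x An `act_icc`.
#' @param ... Unused.
#' @method glance act_icc
#' @export
glance.act_icc <- function(x, ...) {
  tibble::tibble(sigma2_u = x$sigma2_u, icc = x$icc,
                 n_messages = length(x$messages))
}
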