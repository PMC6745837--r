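# Build a minimal valid patient table; every covariate takes its first
# domain level unless overridden.
make_patients <- function(hospital_id, treated, ...) {
  n <- length(hospital_id)
  stopifnot(length(treated) == n)
  defaults <- list(
    age_group = "60-69", sex = "F", ses_quintile = "3", charlson = "0",
    length_of_stay = 8L, t_stage = "T3", n_stage = "N1",
    grade = "well-moderate", lvi = "no", node_harvest = ">=12"
  )
  over <- list(...)
  defaults[names(over)] <- over
  out <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    hospital_id = hospital_id,
    treated = as.integer(treated)
  )
  for (col in names(defaults)) out[[col]] <- rep_len(defaults[[col]], n)
  out
}

make_hospitals <- function(hospital_id, teaching = 0L, cancer_centre = 0L,
                           medonc_onsite = 0L) {
  tibble::tibble(
    hospital_id = hospital_id,
    teaching = rep_len(as.integer(teaching), length(hospital_id)),
    cancer_centre = rep_len(as.integer(cancer_centre), length(hospital_id)),
    medonc_onsite = rep_len(as.integer(medonc_onsite), length(hospital_id))
  )
}

# Cohort with given per-hospital denominators and numerators.
make_count_cohort <- function(n, k, hospital_id = sprintf("H%02d", seq_along(n)),
                              ...) {
  stopifnot(length(n) == length(k), all(k <= n))
  pts <- make_patients(
    hospital_id = rep(hospital_id, times = n),
    treated = unlist(mapply(function(ni, ki) rep(c(1L, 0L), c(ki, ni - ki)),
                            n, k, SIMPLIFY = FALSE)),
    ...
  )
  cohort(pts, make_hospitals(hospital_id))
}

# Exact expected CV (and interval endpoints are not needed) of hospital rates
# under the binomial null, by full enumeration of the outcome space;
# conditional on the CV being defined (mean rate > 0).
enumerate_null_cv <- function(ns, p) {
  grids <- lapply(ns, function(n) 0:n)
  combos <- as.matrix(expand.grid(grids))
  probs <- apply(combos, 1, function(k) prod(stats::dbinom(k, ns, p)))
  rates <- sweep(combos, 2, ns, `/`)
  means <- rowMeans(rates)
  sds <- apply(rates, 1, stats::sd)
  defined <- means > 0
  cvs <- sds[defined] / means[defined]
  w <- probs[defined]
  list(expected_cv = sum(w * cvs) / sum(w),
       p_degenerate = sum(probs[!defined]))
}

# Independent pared-mean oracle: enumerate prefixes of the rank-ordered
# hospital list and take the first whose cumulative size reaches the target.
prefix_oracle <- function(rates_tbl, fraction) {
  ord <- order(-rates_tbl$rate, -rates_tbl$n, rates_tbl$hospital_id)
  sorted <- rates_tbl[ord, ]
  total <- sum(sorted$n)
  for (m in seq_len(nrow(sorted))) {
    if (sum(sorted$n[seq_len(m)]) >= fraction * total) {
      return(sorted$hospital_id[seq_len(m)])
    }
  }
  sorted$hospital_id
}
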