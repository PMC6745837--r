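#' Categorical domains of the patient-level schema
#'
#' Category levels for every discrete covariate in a patient record. "Unknown"
#' style levels (`ses_quintile = "unknown"`, `lvi = "NA"`, `grade =
#' "unstated"`, `node_harvest = "unknown"`) are first-class levels, not
#' missing data: registry tables report them as categories and treating them
#' as such preserves denominators.
#'
#' @return Named list of character vectors, one per categorical column of the
#'   patient table.
#' @export
#' @examples
#' cohort_levels()$charlson
cohort_levels <- function() {
  list(
    age_group    = c("20-49", "50-59", "60-69", "70-79", "80+"),
    sex          = c("F", "M"),
    ses_quintile = c("1", "2", "3", "4", "5", "unknown"),
    charlson     = c("0", "1", "2+"),
    t_stage      = c("T<=1", "T2", "T3", "T4"),
    n_stage      = c("N1", "N2"),
    grade        = c("well-moderate", "poor", "unstated"),
    lvi          = c("no", "yes", "NA"),
    node_harvest = c(">=12", "<12", "unknown")
  )
}

patient_columns <- function() {
  c("patient_id", "hospital_id", "treated", "age_group", "sex",
    "ses_quintile", "charlson", "length_of_stay", "t_stage", "n_stage",
    "grade", "lvi", "node_harvest")
}

hospital_columns <- function() {
  c("hospital_id", "teaching", "cancer_centre", "medonc_onsite")
}

#' Assemble and validate a cohort
#'
#' Bundles a patient-level table and a hospital attribute table into a
#' validated cohort object. Validation checks every categorical value against
#' [cohort_levels()], the binary domains of `treated` and the hospital flags,
#' non-negativity of `length_of_stay`, uniqueness of `patient_id`, and that
#' every patient's `hospital_id` resolves to exactly one hospital row.
#' Offending rows are reported by row number.
#'
#' @param patients Data frame with columns
#'   `patient_id, hospital_id, treated, age_group, sex, ses_quintile,
#'   charlson, length_of_stay, t_stage, n_stage, grade, lvi, node_harvest`.
#' @param hospitals Data frame with columns
#'   `hospital_id, teaching, cancer_centre, medonc_onsite`. `n_cases` is
#'   derived from the patient table and need not be supplied.
#' @return An object of class `act_cohort`: a list with tibbles `patients`
#'   and `hospitals` (the latter gaining a derived `n_cases` column).
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   patient_id = c("P1", "P2"), hospital_id = "H1", treated = c(1L, 0L),
#'   age_group = "60-69", sex = c("F", "M"), ses_quintile = "3",
#'   charlson = "0", length_of_stay = 8L, t_stage = "T3", n_stage = "N1",
#'   grade = "well-moderate", lvi = "no", node_harvest = ">=12"
#' )
#' hosp <- tibble::tibble(hospital_id = "H1", teaching = 0L,
#'                        cancer_centre = 0L, medonc_onsite = 1L)
#' cohort(pts, hosp)
cohort <- function(patients, hospitals) {
  patients <- tibble::as_tibble(patients)
  hospitals <- tibble::as_tibble(hospitals)

  check_columns(patients, patient_columns(), "patients")
  check_columns(hospitals, hospital_columns(), "hospitals")

  problems <- validate_patients(patients)
  problems <- c(problems, validate_hospitals(hospitals))

  missing_hosp <- !patients$hospital_id %in% hospitals$hospital_id
  if (any(missing_hosp)) {
    problems <- c(problems, sprintf(
      "patients row %d: hospital_id '%s' not present in hospital table",
      which(missing_hosp), patients$hospital_id[missing_hosp]
    ))
  }
  if (anyDuplicated(hospitals$hospital_id)) {
    problems <- c(problems, sprintf(
      "hospitals: duplicate hospital_id '%s'",
      unique(hospitals$hospital_id[duplicated(hospitals$hospital_id)])
    ))
  }
  if (length(problems)) {
    abort(c("Cohort validation failed.", setNames(head(problems, 20), rep("x", min(20, length(problems))))),
          class = "act_validation_error")
  }

  counts <- dplyr::count(patients, .data$hospital_id, name = "n_cases")
  hospitals <- hospitals %>%
    dplyr::select(dplyr::all_of(hospital_columns())) %>%
    dplyr::left_join(counts, by = "hospital_id") %>%
    dplyr::mutate(n_cases = dplyr::coalesce(.data$n_cases, 0L))

  structure(list(patients = patients, hospitals = hospitals),
            class = "act_cohort")
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s table is missing column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "act_schema_error")
  }
  invisible(df)
}

validate_patients <- function(patients) {
  problems <- character()
  bad_row <- function(rows, msg) {
    if (any(rows)) sprintf("patients row %d: %s", which(rows), msg) else character()
  }
  lv <- cohort_levels()
  for (col in names(lv)) {
    vals <- as.character(patients[[col]])
    bad <- !(vals %in% lv[[col]]) | is.na(vals)
    if (any(bad)) {
      problems <- c(problems, sprintf(
        "patients row %d: %s value %s outside domain {%s}",
        which(bad), col,
        ifelse(is.na(vals[bad]), "<missing>", sQuote(vals[bad])),
        paste(lv[[col]], collapse = ", ")))
    }
  }
  treated <- patients$treated
  problems <- c(problems, bad_row(!(treated %in% c(0L, 1L)) | is.na(treated),
                                  "treated must be 0 or 1"))
  los <- patients$length_of_stay
  problems <- c(problems, bad_row(is.na(los) | los < 0 | los != floor(los),
                                  "length_of_stay must be a non-negative integer"))
  problems <- c(problems, bad_row(is.na(patients$hospital_id) | patients$hospital_id == "",
                                  "hospital_id must be non-empty"))
  if (anyDuplicated(patients$patient_id)) {
    dup <- duplicated(patients$patient_id)
    problems <- c(problems, bad_row(dup, "duplicate patient_id"))
  }
  problems
}

validate_hospitals <- function(hospitals) {
  problems <- character()
  for (col in c("teaching", "cancer_centre", "medonc_onsite")) {
    bad <- !(hospitals[[col]] %in% c(0L, 1L)) | is.na(hospitals[[col]])
    if (any(bad)) {
      problems <- c(problems, sprintf("hospitals row %d: %s must be 0 or 1",
                                      which(bad), col))
    }
  }
  problems
}

#' Read a cohort from delimited text
#'
#' Reads the comma-separated patient and hospital tables (UTF-8, header row
#' required; see [write_cohort()] for the column layout) and returns a
#' validated cohort. The literal strings `"NA"` and `"unknown"` are category
#' levels, never missing values, so no NA-substitution is applied on read.
#'
#' @param patient_path,hospital_path Paths to `patients.csv` and
#'   `hospitals.csv`.
#' @return An `act_cohort`, as from [cohort()].
#' @export
read_cohort <- function(patient_path, hospital_path) {
  if (!file.exists(patient_path)) abort(sprintf("patient file not found: %s", patient_path))
  if (!file.exists(hospital_path)) abort(sprintf("hospital file not found: %s", hospital_path))
  header <- function(path) readr::read_csv(path, n_max = 0, na = character(),
                                           show_col_types = FALSE)
  check_columns(header(patient_path), patient_columns(), "patients")
  check_columns(header(hospital_path), hospital_columns(), "hospitals")
  patients <- readr::read_csv(
    patient_path, na = character(), show_col_types = FALSE,
    col_types = readr::cols(
      treated = readr::col_integer(),
      length_of_stay = readr::col_integer(),
      .default = readr::col_character()
    )
  )
  hospitals <- readr::read_csv(
    hospital_path, na = character(), show_col_types = FALSE,
    col_types = readr::cols(
      hospital_id = readr::col_character(),
      .default = readr::col_integer()
    )
  )
  hospitals$n_cases <- NULL
  cohort(patients, hospitals)
}

#' Write a cohort to delimited text
#'
#' Writes `patients.csv` (columns `patient_id, hospital_id, treated,
#' age_group, sex, ses_quintile, charlson, length_of_stay, t_stage, n_stage,
#' grade, lvi, node_harvest`) and `hospitals.csv` (`hospital_id, teaching,
#' cancer_centre, medonc_onsite`). Files round-trip exactly through
#' [read_cohort()].
#'
#' @param cohort An `act_cohort`.
#' @param patient_path,hospital_path Output paths.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, patient_path, hospital_path) {
  stopifnot(inherits(cohort, "act_cohort"))
  readr::write_csv(cohort$patients[patient_columns()], patient_path)
  readr::write_csv(cohort$hospitals[hospital_columns()], hospital_path)
  invisible(cohort)
}

#' @export
print.act_cohort <- function(x, ...) {
  cat(sprintf("<act_cohort> %d patients across %d hospitals; treated %d (%.1f%%)\n",
              nrow(x$patients), nrow(x$hospitals), sum(x$patients$treated),
              100 * mean(x$patients$treated)))
  invisible(x)
}

# Patient table of a cohort, or pass a data frame through (data-frame-first
# entry points accept either).
cohort_patients <- function(x) {
  if (inherits(x, "act_cohort")) x$patients else tibble::as_tibble(x)
}
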