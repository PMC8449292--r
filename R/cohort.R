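# Admission-level cohort table: one row per psychiatric admission with
# diagnosis, demographics, Charlson Comorbidity Index, medical-history flags
# and length of stay. Regressions run at admission level; baseline
# characteristics at patient level via the first admission.

#' Allowed diagnosis groups and history flags
#' @keywords internal
diagnosis_levels <- c("depression", "schizophrenia", "bipolar_disorder")

history_flags <- c("htn", "dm", "stroke", "renal", "pneumonia")

cohort_columns <- c(
  "patient_id", "admission_id", "diagnosis", "age", "sex",
  "los_days", "cci", history_flags
)

#' Validate an admission-level cohort table
#'
#' Checks the cohort schema: diagnosis in depression / schizophrenia /
#' bipolar_disorder, sex in female / male, `los_days > 0`, `age >= 0`,
#' `cci >= 0`, 0/1 history flags, unique `admission_id`. Repeat
#' `patient_id`s are allowed (repeat admissions). Violations abort with a
#' message listing the offending rows.
#'
#' @param cohort A data frame with the cohort columns (extra columns, e.g.
#'   joined domain scores, are kept).
#' @return The validated cohort as a tibble.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop_validation("`cohort` must be a data frame")
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols)) {
    stop_validation(paste0("cohort is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  cohort <- as_tibble(cohort)
  cohort$patient_id <- as.character(cohort$patient_id)
  cohort$admission_id <- as.character(cohort$admission_id)

  problems <- character(0)
  bad_rows <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      sprintf("%s (rows %s)", what,
              paste(head(idx, 10L), collapse = ", "))
    } else character(0)
  }
  problems <- c(
    problems,
    bad_rows(!cohort$diagnosis %in% diagnosis_levels, "unknown diagnosis label"),
    bad_rows(!cohort$sex %in% c("female", "male"), "sex must be female/male"),
    bad_rows(!is.finite(cohort$los_days) | cohort$los_days <= 0,
             "los_days must be > 0"),
    bad_rows(!is.finite(cohort$age) | cohort$age < 0, "age must be >= 0"),
    bad_rows(!is.finite(cohort$cci) | cohort$cci < 0, "cci must be >= 0")
  )
  for (fl in history_flags) {
    problems <- c(problems,
                  bad_rows(!cohort[[fl]] %in% c(0, 1),
                           paste0(fl, " must be 0/1")))
  }
  if (anyDuplicated(cohort$admission_id)) {
    dup <- unique(cohort$admission_id[duplicated(cohort$admission_id)])
    problems <- c(problems, paste0("duplicate admission_id: ",
                                   paste(head(dup, 10L), collapse = ", ")))
  }
  if (length(problems)) {
    stop_validation(paste0("invalid cohort:\n  ",
                           paste(problems, collapse = "\n  ")))
  }
  if (anyDuplicated(cohort$patient_id)) {
    inform(paste0(
      "cohort contains repeat admissions (",
      nrow(cohort), " admissions / ",
      dplyr::n_distinct(cohort$patient_id), " patients); ",
      "regressions are unadjusted for within-patient clustering"
    ))
  }
  cohort
}

#' Read an admission-level cohort CSV
#'
#' Expected header:
#' `patient_id,admission_id,diagnosis,age,sex,los_days,cci,htn,dm,stroke,renal,pneumonia`.
#' Extra columns (e.g. pre-joined domain scores) are read as numeric.
#'
#' @param path Cohort CSV path.
#' @return A validated cohort tibble (admission unit).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_format(paste0("cohort file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    admission_id = readr::col_character(),
    diagnosis = readr::col_character(),
    sex = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_cohort(df)
}

#' Write a cohort table to CSV
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Dichotomize length of stay
#'
#' Codes a stay as long (1) iff `los_days` strictly exceeds the threshold.
#' The 3-day default reflects South Korea's involuntary-admission window:
#' stays are analyzed as at most 3 days versus more than 3 days, and a stay
#' of exactly 3 days is coded short.
#'
#' @param los_days Numeric vector of lengths of stay (days).
#' @param threshold Positive threshold in days (default 3).
#' @return Integer vector of 0/1.
#' @export
#' @examples
#' los_binary(c(0.5, 3, 4))
los_binary <- function(los_days, threshold = 3) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_validation("`threshold` must be a single positive number")
  }
  as.integer(los_days > threshold)
}

#' Collapse a cohort to one baseline record per patient
#'
#' Keeps, per `patient_id`, the chronologically first admission; admission
#' order is taken from lexicographic `admission_id` order (admission ids are
#' assigned in admission order). Idempotent, never increases the record
#' count.
#'
#' @param cohort Admission-level cohort tibble.
#' @return A tibble with one row per patient, attribute `unit` set to
#'   `"patient_baseline"`.
#' @export
to_patient_baseline <- function(cohort) {
  out <- cohort |>
    dplyr::arrange(.data$patient_id, .data$admission_id) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE)
  attr(out, "unit") <- "patient_baseline"
  out
}

#' Join domain scores onto a cohort
#'
#' Every admission must have a score row; admissions without scores abort
#' with their ids listed.
#'
#' @param cohort Cohort tibble (admission unit).
#' @param scores Score tibble from [score_notes()] / [read_scores()].
#' @return The cohort with domain score columns appended.
#' @export
join_scores <- function(cohort, scores) {
  missing_ids <- setdiff(cohort$admission_id, scores$admission_id)
  if (length(missing_ids)) {
    stop_validation(paste0(
      "admissions without scores: ",
      paste(head(missing_ids, 10L), collapse = ", "),
      if (length(missing_ids) > 10L) sprintf(" (and %d more)", length(missing_ids) - 10L) else ""
    ))
  }
  dplyr::left_join(cohort, scores, by = "admission_id")
}

# domain score columns present in a cohort/score table
score_columns <- function(df, domains = NULL) {
  if (is.null(domains)) {
    cand <- setdiff(names(df), c(cohort_columns, "admission_id"))
    cand <- cand[vapply(df[cand], is.numeric, logical(1))]
    if (length(cand) == 0L) stop_validation("no domain score columns found")
    cand
  } else {
    missing_cols <- setdiff(domains, names(df))
    if (length(missing_cols)) {
      stop_validation(paste0("score column(s) not in data: ",
                             paste(missing_cols, collapse = ", ")))
    }
    domains
  }
}
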