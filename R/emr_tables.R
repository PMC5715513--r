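# Strict readers/writers for the three flat EMR tables.
#
# All dates are day-resolution ISO-8601; every window in the downstream
# linkage algorithm is expressed in whole calendar days. ICD-10 codes are
# stored dot-free and uppercase ("G45.8" -> "G458").

PATIENT_COLUMNS <- c("patient_id", "birth_date", "death_date", "sex",
                     "cancer_type", "cancer_stage", "registration_date")
DIAGNOSIS_COLUMNS <- c("record_id", "patient_id", "code", "registration_date",
                       "certainty", "position", "department")
PROCEDURE_COLUMNS <- c("record_id", "patient_id", "modality", "order_date")

SEX_LEVELS <- c("male", "female")
STAGE_LEVELS <- c("0", "I", "II", "III", "IV", "unknown")
CERTAINTY_LEVELS <- c("definite", "suspected")
POSITION_LEVELS <- c("primary", "secondary", "other")
MODALITY_LEVELS <- c("CT", "MRI")

read_raw_csv <- function(path, columns) {
  if (!file.exists(path)) {
    phv_abort(sprintf("file not found: %s", path), "phenoval_missing_file")
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL, strip.white = FALSE)
  missing <- setdiff(columns, names(df))
  if (length(missing)) {
    phv_abort(sprintf("%s: missing column(s): %s", path,
                      paste(missing, collapse = ", ")),
              "phenoval_missing_column")
  }
  df[columns]
}

parse_date_column <- function(x, column, path, allow_empty = FALSE) {
  blank <- !nzchar(x)
  out <- as.Date(rep(NA_character_, length(x)))
  parsed <- as.Date(x[!blank], format = "%Y-%m-%d", optional = TRUE)
  # as.Date accepts some malformed strings; require canonical round-trip
  ok <- !is.na(parsed) & format(parsed, "%Y-%m-%d") == x[!blank]
  if (any(!ok)) {
    rows <- which(!blank)[!ok]
    phv_abort(sprintf("%s: column '%s' has unparseable date(s) in row(s) %s",
                      path, column, paste(utils::head(rows, 5L), collapse = ", ")),
              "phenoval_bad_date", rows = rows)
  }
  if (any(blank) && !allow_empty) {
    rows <- which(blank)
    phv_abort(sprintf("%s: column '%s' is empty in row(s) %s",
                      path, column, paste(utils::head(rows, 5L), collapse = ", ")),
              "phenoval_bad_date", rows = rows)
  }
  out[!blank] <- parsed
  out
}

check_enum_column <- function(x, levels, column, path) {
  bad <- !(x %in% levels)
  if (any(bad)) {
    rows <- which(bad)
    phv_abort(sprintf(
      "%s: column '%s' has value(s) outside {%s} in row(s) %s",
      path, column, paste(levels, collapse = ", "),
      paste(utils::head(rows, 5L), collapse = ", ")),
      "phenoval_bad_enum", rows = rows)
  }
  x
}

load_patients_csv <- function(path) {
  df <- read_raw_csv(path, PATIENT_COLUMNS)
  if (nrow(df) == 0L) {
    df$birth_date <- df$death_date <- df$registration_date <- as.Date(character())
    return(df)
  }
  if (any(!nzchar(df$patient_id))) {
    phv_abort(sprintf("%s: empty patient_id in row(s) %s", path,
                      paste(utils::head(which(!nzchar(df$patient_id)), 5L), collapse = ", ")),
              "phenoval_bad_enum")
  }
  df$birth_date <- parse_date_column(df$birth_date, "birth_date", path)
  df$death_date <- parse_date_column(df$death_date, "death_date", path, allow_empty = TRUE)
  df$registration_date <- parse_date_column(df$registration_date, "registration_date", path)
  df$sex <- check_enum_column(df$sex, SEX_LEVELS, "sex", path)
  df$cancer_stage <- check_enum_column(df$cancer_stage, STAGE_LEVELS, "cancer_stage", path)
  df
}

load_diagnoses_csv <- function(path) {
  df <- read_raw_csv(path, DIAGNOSIS_COLUMNS)
  if (nrow(df) == 0L) {
    df$registration_date <- as.Date(character())
    return(df)
  }
  # record_id is the dedup tie-breaker; assign in file order when absent
  blank_id <- !nzchar(df$record_id)
  df$record_id[blank_id] <- sprintf("D%07d", which(blank_id))
  df$code <- normalize_code(df$code)
  df$registration_date <- parse_date_column(df$registration_date, "registration_date", path)
  df$certainty <- check_enum_column(df$certainty, CERTAINTY_LEVELS, "certainty", path)
  df$position <- check_enum_column(df$position, POSITION_LEVELS, "position", path)
  df$department[!nzchar(df$department)] <- NA_character_
  df
}

load_procedures_csv <- function(path) {
  df <- read_raw_csv(path, PROCEDURE_COLUMNS)
  if (nrow(df) == 0L) {
    df$order_date <- as.Date(character())
    return(df)
  }
  blank_id <- !nzchar(df$record_id)
  df$record_id[blank_id] <- sprintf("R%07d", which(blank_id))
  df$modality <- check_enum_column(df$modality, MODALITY_LEVELS, "modality", path)
  df$order_date <- parse_date_column(df$order_date, "order_date", path)
  df
}

#' Assemble an EMR bundle from the three tables
#'
#' An `emr_bundle` holds the patient registry, the diagnosis-code
#' registrations and the imaging orders as three data frames with parsed
#' dates and normalized ICD-10 codes. Referential integrity (every
#' `patient_id` used in diagnoses/procedures exists in the registry) is
#' checked on construction.
#'
#' @param patients,diagnoses,procedures data frames with the documented
#'   columns (see [load_bundle()] for the CSV schemas).
#' @param check check referential integrity (default `TRUE`).
#' @return An object of class `emr_bundle`: a list with elements
#'   `patients`, `diagnoses`, `procedures`.
#' @export
emr_bundle <- function(patients, diagnoses, procedures, check = TRUE) {
  out <- structure(list(patients = patients, diagnoses = diagnoses,
                        procedures = procedures),
                   class = "emr_bundle")
  if (check) {
    ids <- unique(patients$patient_id)
    orphan_d <- setdiff(diagnoses$patient_id, ids)
    orphan_p <- setdiff(procedures$patient_id, ids)
    if (length(orphan_d) || length(orphan_p)) {
      phv_abort(sprintf(
        "patient_id(s) absent from the registry: %s",
        paste(utils::head(c(orphan_d, orphan_p), 5L), collapse = ", ")),
        "phenoval_integrity_error")
    }
  }
  out
}

#' @export
print.emr_bundle <- function(x, ...) {
  cat("<emr_bundle>\n")
  cat(sprintf("  patients:   %d\n", nrow(x$patients)))
  cat(sprintf("  diagnoses:  %d\n", nrow(x$diagnoses)))
  cat(sprintf("  procedures: %d\n", nrow(x$procedures)))
  invisible(x)
}

#' Load an EMR bundle from three CSV files
#'
#' Strict, schema-validated readers. Expected headers:
#' \describe{
#'   \item{patients.csv}{`patient_id,birth_date,death_date,sex,cancer_type,cancer_stage,registration_date`}
#'   \item{diagnoses.csv}{`record_id,patient_id,code,registration_date,certainty,position,department`}
#'   \item{procedures.csv}{`record_id,patient_id,modality,order_date`}
#' }
#' Dates must be ISO-8601 (`YYYY-MM-DD`); an empty `death_date` means alive.
#' Diagnosis codes are normalized on load (uppercase, dot removed), and
#' empty `record_id` values are assigned in file order. Rows violating the
#' schema never pass silently: each failure mode raises a classed error
#' (`phenoval_missing_file`, `phenoval_missing_column`, `phenoval_bad_date`,
#' `phenoval_bad_enum`) naming the offending rows.
#'
#' @param patients_path,diagnoses_path,procedures_path CSV file paths.
#' @param check check referential integrity across tables.
#' @return An [emr_bundle()].
#' @export
load_bundle <- function(patients_path, diagnoses_path, procedures_path,
                        check = TRUE) {
  emr_bundle(load_patients_csv(patients_path),
             load_diagnoses_csv(diagnoses_path),
             load_procedures_csv(procedures_path),
             check = check)
}

format_date_out <- function(x) {
  out <- format(x, "%Y-%m-%d")
  out[is.na(x)] <- ""
  out
}

#' Write an EMR bundle to a directory of CSV files
#'
#' Inverse of [load_bundle()]: `load_bundle()` applied to the written files
#' reproduces the bundle field-for-field. Output is byte-stable for a given
#' bundle (fixed column order, ISO dates, empty string for missing values).
#'
#' @param bundle an [emr_bundle()].
#' @param directory output directory, created if needed.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "emr_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) {
    phv_abort(sprintf("cannot create directory: %s", directory),
              "phenoval_unwritable_path")
  }
  paths <- c(patients = file.path(directory, "patients.csv"),
             diagnoses = file.path(directory, "diagnoses.csv"),
             procedures = file.path(directory, "procedures.csv"))
  p <- bundle$patients
  p$birth_date <- format_date_out(p$birth_date)
  p$death_date <- format_date_out(p$death_date)
  p$registration_date <- format_date_out(p$registration_date)
  d <- bundle$diagnoses
  d$registration_date <- format_date_out(d$registration_date)
  d$department[is.na(d$department)] <- ""
  pr <- bundle$procedures
  pr$order_date <- format_date_out(pr$order_date)
  utils::write.csv(p[PATIENT_COLUMNS], paths[["patients"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(d[DIAGNOSIS_COLUMNS], paths[["diagnoses"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(pr[PROCEDURE_COLUMNS], paths[["procedures"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
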