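# Core phenotyping algorithm: same-day deduplication of diagnostic-code
# registrations and classification of each deduplicated record into
# overlapping algorithm arms via temporal linkage to brain-imaging orders.

POSITION_RANK <- c(primary = 1L, secondary = 2L, other = 3L)

#' Define a phenotyping algorithm arm
#'
#' An arm selects deduplicated code records by certainty flag and, optionally,
#' by the patient's brain-imaging history: none required, any imaging order
#' for the patient, or an imaging order within `window` calendar days of the
#' code's registration date.
#'
#' @param name arm label (used as a column name in the assignment table).
#' @param certainty `"definite"` or `"suspected"`.
#' @param imaging `"not_required"`, `"any"`, or `"within_days"`.
#' @param window non-negative whole-day window; required when
#'   `imaging = "within_days"`.
#' @param direction window direction: `"two_sided"` (|offset| <= window,
#'   the default), `"after_only"` (imaging on or after the code date) or
#'   `"before_only"`.
#' @return Object of class `arm_spec`.
#' @export
arm_spec <- function(name, certainty, imaging = c("not_required", "any", "within_days"),
                     window = NULL,
                     direction = c("two_sided", "after_only", "before_only")) {
  imaging <- match.arg(imaging)
  direction <- match.arg(direction)
  certainty <- match.arg(certainty, CERTAINTY_LEVELS)
  if (imaging == "within_days") {
    if (is.null(window) || length(window) != 1L || is.na(window) || window < 0) {
      phv_abort("`window` must be a single non-negative whole number of days",
                "phenoval_bad_config")
    }
    window <- as.integer(window)
  } else {
    window <- NA_integer_
  }
  structure(list(name = name, certainty = certainty, imaging = imaging,
                 window = window, direction = direction),
            class = "arm_spec")
}

#' The five shipped algorithm arms
#'
#' Definite code alone; definite plus any brain imaging; definite plus
#' imaging within 30 days; definite plus imaging within 1 day; suspected
#' plus any brain imaging.
#'
#' @param direction window direction applied to the windowed arms.
#' @return Named list of [arm_spec()] objects.
#' @export
default_arm_specs <- function(direction = "two_sided") {
  specs <- list(
    arm_spec("definite", "definite", "not_required"),
    arm_spec("definite_any_imaging", "definite", "any"),
    arm_spec("definite_imaging_30d", "definite", "within_days", 30L, direction),
    arm_spec("definite_imaging_1d", "definite", "within_days", 1L, direction),
    arm_spec("suspected_any_imaging", "suspected", "any"))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Remove same-day duplicate code registrations
#'
#' A duplicate is the same diagnostic code registered more than once for the
#' same patient on the same day (e.g. by different departments); keeping
#' them would overcount the apparent disease burden. Within each duplicate
#' group the survivor is the record with the highest position rank
#' (primary > secondary > other), ties broken by record order. Definite and
#' suspected registrations are deduplicated independently.
#'
#' @param records diagnosis table with normalized codes.
#' @return Subset of `records`, unique on
#'   (`patient_id`, `code`, `registration_date`, `certainty`), in input order.
#' @export
dedup_diagnoses <- function(records) {
  n <- nrow(records)
  if (n == 0L) return(records)
  key <- paste(records$patient_id, records$code,
               format(records$registration_date, "%Y-%m-%d"),
               records$certainty, sep = "\r")
  rank <- POSITION_RANK[records$position]
  ord <- order(key, rank, seq_len(n))
  keep_in_ord <- !duplicated(key[ord])
  records[sort(ord[keep_in_ord]), , drop = FALSE]
}

#' Signed day offset from a code record to the nearest imaging order
#'
#' Offset is `order_date - registration_date` in whole days. The nearest
#' order is the one with the smallest absolute offset; an exact tie between
#' a past and a future order resolves to the non-negative offset. `NA` when
#' the patient has no imaging.
#'
#' @param record one diagnosis record (one-row data frame or list with
#'   `patient_id` and `registration_date`).
#' @param procedures procedure table (any patients; filtered internally).
#' @return Integer offset in days, or `NA_integer_`.
#' @export
nearest_imaging_offset <- function(record, procedures) {
  dates <- procedures$order_date[procedures$patient_id == record$patient_id]
  if (length(dates) == 0L) return(NA_integer_)
  off <- as.integer(dates - as.Date(record$registration_date))
  decode_nearest(min(encode_offset(off)))
}

# Order-preserving encoding: smaller key = nearer, with the non-negative
# offset winning an absolute tie.
encode_offset <- function(off) abs(off) * 2L + as.integer(off < 0L)
decode_nearest <- function(key) {
  off <- key %/% 2L
  if (key %% 2L == 1L) -off else off
}

# Vectorized per-record imaging summaries via a patient-level join.
imaging_summaries <- function(records, procedures) {
  n <- nrow(records)
  out <- data.frame(has_imaging = logical(n),
                    nearest_offset = rep(NA_integer_, n),
                    nearest_after = rep(NA_integer_, n),
                    nearest_before = rep(NA_integer_, n))
  if (n == 0L || nrow(procedures) == 0L) return(out)
  rec <- data.frame(i = seq_len(n), patient_id = records$patient_id,
                    registration_date = records$registration_date,
                    stringsAsFactors = FALSE)
  pairs <- merge(rec,
                 data.frame(patient_id = procedures$patient_id,
                            order_date = procedures$order_date,
                            stringsAsFactors = FALSE),
                 by = "patient_id")
  if (nrow(pairs) == 0L) return(out)
  off <- as.integer(pairs$order_date - pairs$registration_date)
  key <- encode_offset(off)
  nearest <- tapply(key, pairs$i, min)
  idx <- as.integer(names(nearest))
  out$has_imaging[idx] <- TRUE
  out$nearest_offset[idx] <- vapply(as.integer(nearest), decode_nearest, integer(1))
  aft <- tapply(ifelse(off >= 0L, off, NA_integer_), pairs$i,
                function(x) if (all(is.na(x))) NA_integer_ else min(x, na.rm = TRUE))
  bef <- tapply(ifelse(off <= 0L, off, NA_integer_), pairs$i,
                function(x) if (all(is.na(x))) NA_integer_ else max(x, na.rm = TRUE))
  out$nearest_after[idx] <- as.integer(aft)
  out$nearest_before[idx] <- as.integer(bef)
  out
}

arm_window_hit <- function(spec, summ) {
  switch(spec$direction,
         two_sided = !is.na(summ$nearest_offset) & abs(summ$nearest_offset) <= spec$window,
         after_only = !is.na(summ$nearest_after) & summ$nearest_after <= spec$window,
         before_only = !is.na(summ$nearest_before) & -summ$nearest_before <= spec$window)
}

#' Classify deduplicated code records into algorithm arms
#'
#' For each record, membership in each arm is: certainty flag matches, and
#' the arm's imaging requirement holds — trivially for `not_required`, any
#' imaging order for the patient for `any`, or an imaging order within the
#' arm's day window of the registration date for `within_days`. Arms
#' overlap by construction; each is reviewed independently downstream.
#'
#' @param records deduplicated diagnosis records (see [dedup_diagnoses()]).
#' @param procedures imaging-order table.
#' @param arm_specs named list of [arm_spec()]s (default the five shipped arms).
#' @return Data frame of class `arm_assignment`: the records plus
#'   `nearest_offset` (signed days to the closest imaging order, `NA` if
#'   none) and one logical column per arm. Arm names are stored in
#'   `attr(, "arm_names")`.
#' @export
classify_arms <- function(records, procedures, arm_specs = default_arm_specs()) {
  if (is.null(names(arm_specs)) || anyDuplicated(names(arm_specs))) {
    names(arm_specs) <- vapply(arm_specs, `[[`, "", "name")
  }
  if (anyDuplicated(names(arm_specs))) {
    phv_abort("arm names must be unique", "phenoval_unknown_arm")
  }
  clash <- intersect(names(arm_specs), names(records))
  if (length(clash)) {
    phv_abort(sprintf("arm name(s) collide with record columns: %s",
                      paste(clash, collapse = ", ")), "phenoval_unknown_arm")
  }
  summ <- imaging_summaries(records, procedures)
  out <- records
  out$nearest_offset <- summ$nearest_offset
  for (spec in arm_specs) {
    stopifnot(inherits(spec, "arm_spec"))
    cert_ok <- records$certainty == spec$certainty
    img_ok <- switch(spec$imaging,
                     not_required = rep(TRUE, nrow(records)),
                     any = summ$has_imaging,
                     within_days = arm_window_hit(spec, summ))
    out[[spec$name]] <- cert_ok & img_ok
  }
  structure(out, arm_names = names(arm_specs), class = c("arm_assignment", "data.frame"))
}

arm_names <- function(assignments) {
  nm <- attr(assignments, "arm_names")
  if (is.null(nm)) {
    phv_abort("not an arm assignment table", "phenoval_unknown_arm")
  }
  nm
}

#' Count records per arm
#'
#' @param assignments a [classify_arms()] result.
#' @return Named integer vector of record counts, one per arm. Windowed
#'   arms nest: within-1 <= within-30 <= any imaging <= certainty alone.
#' @export
arm_counts <- function(assignments) {
  nm <- arm_names(assignments)
  vapply(nm, function(a) sum(assignments[[a]]), integer(1))
}

#' Extract the records belonging to one arm
#'
#' @param assignments a [classify_arms()] result.
#' @param arm arm name.
#' @return Subset of `assignments` rows where the arm flag is `TRUE`.
#' @export
arm_records <- function(assignments, arm) {
  if (!(arm %in% arm_names(assignments))) {
    phv_abort(sprintf("unknown arm: %s (known: %s)", arm,
                      paste(arm_names(assignments), collapse = ", ")),
              "phenoval_unknown_arm")
  }
  assignments[assignments[[arm]], , drop = FALSE]
}
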