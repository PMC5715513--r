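# Deterministic exact-count fixture: realizes a specified flow of registry
# rows, deduplicated code counts and imaging-linkage arm sizes, so the
# pipeline applied to the fixture reproduces the specified counts exactly.

#' Specify an exact-count fixture
#'
#' Defaults encode the worked-example flow the package documents: a
#' 27,932-row registry containing 2,083 repeat registrations and 22
#' impossible-date rows (25,827 retained); 1,991 definite stroke-code
#' records collapsing to 912 distinct same-day events and 663 suspected
#' records collapsing to 228; and definite-arm imaging linkage of
#' 438 (any) / 239 (within 30 days) / 212 (within 1 day). All suspected
#' events carry same-day imaging.
#'
#' @param registry_rows total registry rows before cleaning.
#' @param duplicate_rows repeat-registration rows among them.
#' @param invalid_date_rows rows whose death date precedes birth.
#' @param distinct_definite,total_definite distinct definite (patient,
#'   code, day) events and total definite records including same-day
#'   re-registrations.
#' @param distinct_suspected,total_suspected likewise for suspected codes.
#' @param n_any_imaging,n_within_30,n_within_1 definite events whose
#'   patient has any brain imaging / imaging within 30 days / within 1 day.
#' @param seed integer seed (used only to permute the emitted row order;
#'   the realized counts are exact by construction).
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(registry_rows = 27932L, duplicate_rows = 2083L,
                         invalid_date_rows = 22L,
                         distinct_definite = 912L, total_definite = 1991L,
                         distinct_suspected = 228L, total_suspected = 663L,
                         n_any_imaging = 438L, n_within_30 = 239L,
                         n_within_1 = 212L, seed = 1L) {
  spec <- list(registry_rows = as.integer(registry_rows),
               duplicate_rows = as.integer(duplicate_rows),
               invalid_date_rows = as.integer(invalid_date_rows),
               distinct_definite = as.integer(distinct_definite),
               total_definite = as.integer(total_definite),
               distinct_suspected = as.integer(distinct_suspected),
               total_suspected = as.integer(total_suspected),
               n_any_imaging = as.integer(n_any_imaging),
               n_within_30 = as.integer(n_within_30),
               n_within_1 = as.integer(n_within_1),
               seed = check_seed(seed))
  if (any(vapply(spec, is.na, logical(1))) || any(unlist(spec[1:10]) < 0L)) {
    phv_abort("fixture counts must be non-negative integers",
              "phenoval_infeasible_fixture")
  }
  base <- spec$registry_rows - spec$duplicate_rows - spec$invalid_date_rows
  if (base < spec$distinct_definite + spec$distinct_suspected) {
    phv_abort("registry too small for the requested distinct code events",
              "phenoval_infeasible_fixture")
  }
  if (spec$duplicate_rows > base) {
    phv_abort("more duplicate rows than unique patients to repeat",
              "phenoval_infeasible_fixture")
  }
  if (spec$total_definite < spec$distinct_definite ||
      spec$total_suspected < spec$distinct_suspected ||
      (spec$distinct_definite == 0L && spec$total_definite > 0L) ||
      (spec$distinct_suspected == 0L && spec$total_suspected > 0L)) {
    phv_abort("total records must be >= distinct events (and 0 when no events)",
              "phenoval_infeasible_fixture")
  }
  if (!(spec$n_within_1 <= spec$n_within_30 &&
        spec$n_within_30 <= spec$n_any_imaging &&
        spec$n_any_imaging <= spec$distinct_definite)) {
    phv_abort("imaging counts must nest: within-1 <= within-30 <= any <= distinct definite",
              "phenoval_infeasible_fixture")
  }
  structure(spec, class = "fixture_spec")
}

fixture_truth_codes <- function(n_w1, n_w30, n_any, n_total) {
  # deterministic truth gradient: near-imaging events are mostly true,
  # no-imaging events are all false
  truth <- rep("not_acute_cvd", n_total)
  if (n_w1 > 0L) truth[seq_len(round(0.9 * n_w1))] <- "acute_cvd"
  if (n_w30 > n_w1) {
    block <- (n_w1 + 1L):n_w30
    truth[utils::head(block, round(0.4 * length(block)))] <- "acute_cvd"
  }
  if (n_any > n_w30) {
    block <- (n_w30 + 1L):n_any
    truth[utils::head(block, round(0.11 * length(block)))] <- "acute_cvd"
  }
  truth
}

#' Generate an exact-count fixture bundle
#'
#' Each definite event lives on its own patient, so patient-level imaging
#' linkage realizes the arm counts exactly: the first `n_within_1` events
#' carry imaging at offsets 0/+1/-1, the next `n_within_30 - n_within_1`
#' at +/-14 days, the next `n_any_imaging - n_within_30` at +/-45 days,
#' and the rest none. Same-day re-registrations are distributed round-robin
#' over the events so deduplication recovers the distinct counts exactly.
#' Latent truth follows a deterministic gradient (90% of within-1-day
#' events true, 40% of the within-30-only block, 11% of the any-only
#' block, none of the unimaged events; 7% of suspected events).
#'
#' @param spec a [fixture_spec()].
#' @return List with `bundle`, `truth` (as in [generate_cohort()]) and
#'   `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  win <- study_window()
  base_n <- spec$registry_rows - spec$duplicate_rows - spec$invalid_date_rows
  ndays <- as.integer(win[2] - win[1]) - 400L

  reg <- win[1] + (seq_len(base_n) * 37L) %% ndays
  patients <- data.frame(patient_id = sprintf("P%06d", seq_len(base_n)),
                         birth_date = reg - 22000L,
                         death_date = as.Date(rep(NA_character_, base_n)),
                         sex = rep_len(c("female", "male"), base_n),
                         cancer_type = "others", cancer_stage = "unknown",
                         registration_date = reg, stringsAsFactors = FALSE)
  registry <- patients
  if (spec$duplicate_rows > 0L) {
    dup <- patients[seq_len(spec$duplicate_rows), , drop = FALSE]
    dup$registration_date <- dup$registration_date + 30L
    registry <- rbind(registry, dup)
  }
  if (spec$invalid_date_rows > 0L) {
    k <- spec$invalid_date_rows
    birth <- as.Date("1955-06-01") + seq_len(k) * 50L
    registry <- rbind(registry, data.frame(
      patient_id = sprintf("PX%05d", seq_len(k)),
      birth_date = birth, death_date = birth - 7L,
      sex = rep_len(c("male", "female"), k),
      cancer_type = "others", cancer_stage = "unknown",
      registration_date = win[1] + 1000L, stringsAsFactors = FALSE))
  }

  build_events <- function(n, patient_offset, certainty) {
    if (n == 0L) return(NULL)
    i <- seq_len(n)
    data.frame(patient_id = sprintf("P%06d", patient_offset + i),
               code = rep_len(c("I639", "I619", "I609", "G458", "G459"), n),
               registration_date = reg[patient_offset + i] + (i %% 180L),
               certainty = certainty,
               position = ifelse(i %% 14L == 1L, "primary",
                                 ifelse(i %% 2L == 0L, "secondary", "other")),
               department = "neurology", stringsAsFactors = FALSE)
  }
  def <- build_events(spec$distinct_definite, 0L, "definite")
  sus <- build_events(spec$distinct_suspected, spec$distinct_definite, "suspected")

  # imaging offsets per definite event index
  def_offset <- rep(NA_integer_, spec$distinct_definite)
  if (spec$n_within_1 > 0L) {
    def_offset[seq_len(spec$n_within_1)] <-
      rep_len(c(0L, 1L, -1L), spec$n_within_1)
  }
  if (spec$n_within_30 > spec$n_within_1) {
    block <- (spec$n_within_1 + 1L):spec$n_within_30
    def_offset[block] <- rep_len(c(14L, -14L), length(block))
  }
  if (spec$n_any_imaging > spec$n_within_30) {
    block <- (spec$n_within_30 + 1L):spec$n_any_imaging
    def_offset[block] <- rep_len(c(45L, -45L), length(block))
  }
  sus_offset <- rep(0L, spec$distinct_suspected)

  expand_extras <- function(events, total) {
    n_extra <- total - nrow(events)
    if (n_extra <= 0L) return(NULL)
    e <- events[rep_len(seq_len(nrow(events)), n_extra), , drop = FALSE]
    e$position <- "other"
    e$department <- "second_department"
    e
  }
  def_truth <- fixture_truth_codes(spec$n_within_1, spec$n_within_30,
                                   spec$n_any_imaging, spec$distinct_definite)
  sus_truth <- rep("not_acute_cvd", spec$distinct_suspected)
  if (spec$distinct_suspected > 0L) {
    sus_truth[seq_len(round(0.07 * spec$distinct_suspected))] <- "acute_cvd"
  }

  annotate <- function(events, truth, offset) {
    if (is.null(events)) return(NULL)
    events$truth <- truth
    events$category <- NA_character_
    neg <- truth == "not_acute_cvd"
    has_img <- !is.na(offset)
    events$category[neg & has_img] <- "stroke_mimic"
    events$category[neg & !has_img] <-
      rep_len(c("history_of_stroke", "blood_or_imaging_tests"),
              sum(neg & !has_img))
    events$mimic_subtype <- NA_character_
    mim <- !is.na(events$category) & events$category == "stroke_mimic"
    events$mimic_subtype[mim] <- rep_len(MIMIC_SUBTYPES, sum(mim))
    events$img_offset <- offset
    events
  }
  def <- annotate(def, def_truth, def_offset)
  sus <- annotate(sus, sus_truth, sus_offset)
  events <- rbind(def, sus)
  extras <- rbind(expand_extras(def, spec$total_definite),
                  expand_extras(sus, spec$total_suspected))
  stroke <- rbind(events, extras)

  diag_cols <- c("patient_id", "code", "registration_date", "certainty",
                 "position", "department")
  diagnoses <- if (is.null(stroke)) {
    data.frame(record_id = character(), patient_id = character(),
               code = character(), registration_date = as.Date(character()),
               certainty = character(), position = character(),
               department = character(), stringsAsFactors = FALSE)
  } else {
    d <- cbind(record_id = sprintf("D%07d", seq_len(nrow(stroke))),
               stroke[diag_cols], stringsAsFactors = FALSE)
    perm <- local_seed(spec$seed, sample.int(nrow(d)))
    d[perm, , drop = FALSE]
  }
  truth <- if (is.null(stroke)) {
    data.frame(record_id = character(), truth = character(),
               category = character(), mimic_subtype = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(record_id = sprintf("D%07d", seq_len(nrow(stroke))),
               truth = stroke$truth, category = stroke$category,
               mimic_subtype = stroke$mimic_subtype, stringsAsFactors = FALSE)
  }

  with_img <- if (is.null(events)) NULL else
    events[!is.na(events$img_offset), , drop = FALSE]
  procedures <- if (is.null(with_img) || nrow(with_img) == 0L) {
    data.frame(record_id = character(), patient_id = character(),
               modality = character(), order_date = as.Date(character()),
               stringsAsFactors = FALSE)
  } else {
    data.frame(record_id = sprintf("R%07d", seq_len(nrow(with_img))),
               patient_id = with_img$patient_id,
               modality = rep_len(c("MRI", "CT"), nrow(with_img)),
               order_date = with_img$registration_date + with_img$img_offset,
               stringsAsFactors = FALSE)
  }
  rownames(registry) <- rownames(diagnoses) <- rownames(procedures) <- NULL
  list(bundle = emr_bundle(registry, diagnoses, procedures),
       truth = truth, spec = spec)
}

#' Load a fixture specification from YAML
#'
#' @param path YAML file whose keys are [fixture_spec()] arguments.
#' @param seed optional seed override.
#' @return A [fixture_spec()].
#' @export
read_fixture_spec <- function(path, seed = NULL) {
  args <- yaml::read_yaml(path)
  if (!is.null(seed)) args$seed <- seed
  do.call(fixture_spec, args)
}
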