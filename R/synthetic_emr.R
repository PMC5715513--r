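# Synthetic EMR generator: stands in for the hospital database and the
# manual chart review. Every stroke-code record it emits traces to exactly
# one generating mechanism, and the latent truth table plays the role of a
# perfect reviewer.
#
# Mechanisms (per patient, independent Bernoulli):
#   true_event  - an acute cerebrovascular event: definite code, imaging
#                 almost always on the day of the event or adjacent days.
#   history     - a history-of-stroke code carried forward: truth negative,
#                 imaging absent or far from the code date.
#   mimic       - a stroke mimic coded as stroke: truth negative, imaging
#                 present for a minority and mostly distant.
#   testonly    - a code registered only to justify blood/imaging tests:
#                 truth negative, imaging often present but unrelated in time.
#   ruleout     - a rule-out work-up: suspected code, imaging essentially
#                 always, truth positive only rarely.

MIMIC_SUBTYPES <- c("cervical_spondylotic_myelopathy", "seizure", "dementia",
                    "disturbance_of_consciousness", "syncope",
                    "vestibular_dysfunction", "brain_tumor",
                    "acute_mononeuropathy", "toxic_metabolic",
                    "functional_unexplained", "sudden_severe_headache",
                    "ophthalmic_disorder")
# Pooled non-disease breakdown counts across the four reviewed definite arms
MIMIC_SUBTYPE_WEIGHTS <- c(7, 5, 4, 10, 7, 4, 9, 2, 2, 1, 4, 3)

STROKE_CODE_POOL <- c("I600", "I609", "I610", "I619", "I633", "I635", "I639",
                      "G458", "G459")
STROKE_CODE_WEIGHTS <- c(0.03, 0.05, 0.06, 0.12, 0.10, 0.10, 0.40, 0.06, 0.08)

# Registered code position: primary for a small minority of stroke-code
# registrations in a cancer hospital, as observed in the review samples.
POSITION_PROBS <- c(primary = 0.07, secondary = 0.55, other = 0.38)

#' Per-mechanism imaging-offset models
#'
#' Each model gives the probability that a record's patient has no
#' mechanism-linked brain imaging (`p_none`) and, otherwise, a discrete
#' distribution over signed day offsets (imaging date minus code date).
#' Defaults are back-solved from the arm-size/PPV gradient of a validated
#' hospital pipeline: true events image at the event (95% within a day),
#' mimics image rarely and mostly far from the code date, history codes
#' image long before or after, test-only codes image at unrelated times,
#' and rule-out work-ups always image near the code date.
#'
#' @return Named list of models (`p_none`, `offsets`, `probs`).
#' @export
default_offset_models <- function() {
  list(
    true_event = list(p_none = 0.02,
                      offsets = c(-1L, 0L, 1L, 20L, 45L),
                      probs = c(0.07, 0.80, 0.10, 0.02, 0.01)),
    mimic = list(p_none = 0.63,
                 offsets = c(-60L, -1L, 0L, 1L, 14L, 90L),
                 probs = c(0.30, 0.06, 0.13, 0.07, 0.06, 0.38)),
    history = list(p_none = 0.81,
                   offsets = c(-120L, -20L, 0L, 60L, 200L),
                   probs = c(0.30, 0.08, 0.03, 0.30, 0.29)),
    testonly = list(p_none = 0.49,
                    offsets = c(-150L, -40L, 10L, 75L),
                    probs = c(0.30, 0.30, 0.10, 0.30)),
    ruleout = list(p_none = 0.00,
                   offsets = c(-1L, 0L, 1L, 2L, 7L),
                   probs = c(0.10, 0.50, 0.20, 0.10, 0.10)))
}

default_cancer_type_weights <- function() {
  c(breast = 0.113, uterus = 0.091, colorectal = 0.081, gastric = 0.079,
    lung = 0.065, brain = 0.063, prostate = 0.063, esophageal = 0.054,
    hepatic = 0.043, oropharyngeal = 0.040, others = 0.308)
}

default_stage_weights <- function() {
  w <- c("0" = 6.1, I = 31.2, II = 15.8, III = 11.5, IV = 15.5, unknown = 20.9)
  w / sum(w)
}

check_prob <- function(x, what) {
  if (length(x) < 1L || anyNA(x) || any(x < 0) || any(x > 1)) {
    phv_abort(sprintf("`%s` must be probabilit%s in [0, 1]", what,
                      if (length(x) > 1L) "ies" else "y"),
              "phenoval_bad_config")
  }
  x
}

check_offset_model <- function(m, what) {
  check_prob(m$p_none, paste0(what, "$p_none"))
  if (length(m$offsets) != length(m$probs) || any(m$probs < 0) ||
      abs(sum(m$probs) - 1) > 1e-8) {
    phv_abort(sprintf("`%s` offsets/probs malformed", what), "phenoval_bad_config")
  }
  m$offsets <- as.integer(m$offsets)
  m
}

#' Configure the synthetic EMR generator
#'
#' The defaults emulate the hospital-based cancer registry the pipeline is
#' designed for: 25,827 retained patients (49.5% women, age 61.6 +/- 15.7
#' years at registration, cancer-type mix of a comprehensive cancer
#' centre), registrations uniform over 2007-01-01..2015-12-31, and
#' per-patient mechanism rates sized so the definite stroke-code stream
#' deduplicates to roughly 900 records with the characteristic
#' 22% / 51% / 84% / 90% PPV gradient across the imaging-linkage arms.
#'
#' @param n_patients unique patients in the registry after cleaning.
#' @param duplicate_patient_count,invalid_date_count rows injected before
#'   cleaning: repeated registrations of existing patients, and rows whose
#'   death date precedes their birth date.
#' @param female_fraction,age_mean,age_sd cohort demographics.
#' @param cancer_type_weights named sampling weights over cancer types
#'   (must include `prostate` and `uterus`, which are made sex-consistent).
#' @param stage_weights named weights over stages 0/I/II/III/IV/unknown.
#' @param true_event_rate,history_coding_rate,mimic_rate,testonly_coding_rate
#'   per-patient probabilities of one definite stroke-code record arising
#'   from each mechanism.
#' @param ruleout_suspected_rate per-patient probability of a suspected
#'   (rule-out) stroke-code record.
#' @param ruleout_true_prob probability a rule-out record is truly acute
#'   cerebrovascular disease.
#' @param imaging_offset_models see [default_offset_models()].
#' @param background_imaging_rate probability a non-brain-cancer patient
#'   has one unrelated brain-imaging order; brain-tumour patients always
#'   receive surveillance imaging.
#' @param same_day_duplication_prob named probabilities (`definite`,
#'   `suspected`) that a code registration acquires a further same-day
#'   registration by another department; repeated geometrically, so the
#'   expected number of extra copies is p/(1-p).
#' @param comorbidity_rates named per-patient rates for the covariate code
#'   sets (hypertension, diabetes, dyslipidemia, atrial_fibrillation,
#'   brain_metastases).
#' @param death_rate fraction of patients with a recorded death date.
#' @param seed mandatory integer seed; ordered sub-streams are derived from
#'   it per table and per mechanism, so changing one mechanism's rate does
#'   not perturb the draws of the others.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 25827L,
                             duplicate_patient_count = 0L,
                             invalid_date_count = 0L,
                             female_fraction = 0.495,
                             age_mean = 61.6, age_sd = 15.7,
                             cancer_type_weights = default_cancer_type_weights(),
                             stage_weights = default_stage_weights(),
                             true_event_rate = 0.0078,
                             history_coding_rate = 0.0145,
                             mimic_rate = 0.0078,
                             testonly_coding_rate = 0.0053,
                             ruleout_suspected_rate = 0.0088,
                             ruleout_true_prob = 0.07,
                             imaging_offset_models = default_offset_models(),
                             background_imaging_rate = 0.02,
                             same_day_duplication_prob = c(definite = 0.54, suspected = 0.66),
                             comorbidity_rates = c(hypertension = 0.203,
                                                   diabetes = 0.175,
                                                   dyslipidemia = 0.127,
                                                   atrial_fibrillation = 0.033,
                                                   brain_metastases = 0.018),
                             death_rate = 0.08,
                             seed) {
  seed <- check_seed(seed)
  if (n_patients < 1L) phv_abort("`n_patients` must be >= 1", "phenoval_bad_config")
  check_prob(female_fraction, "female_fraction")
  check_prob(c(true_event_rate, history_coding_rate, mimic_rate,
               testonly_coding_rate, ruleout_suspected_rate),
             "mechanism rates")
  check_prob(ruleout_true_prob, "ruleout_true_prob")
  check_prob(background_imaging_rate, "background_imaging_rate")
  check_prob(death_rate, "death_rate")
  if (length(same_day_duplication_prob) == 1L && is.null(names(same_day_duplication_prob))) {
    same_day_duplication_prob <- c(definite = unname(same_day_duplication_prob),
                                   suspected = unname(same_day_duplication_prob))
  }
  if (!all(c("definite", "suspected") %in% names(same_day_duplication_prob))) {
    phv_abort("`same_day_duplication_prob` needs 'definite' and 'suspected' entries",
              "phenoval_bad_config")
  }
  check_prob(same_day_duplication_prob, "same_day_duplication_prob")
  if (any(same_day_duplication_prob >= 1)) {
    phv_abort("`same_day_duplication_prob` must be < 1", "phenoval_bad_config")
  }
  if (!all(c("prostate", "uterus") %in% names(cancer_type_weights))) {
    phv_abort("`cancer_type_weights` must include 'prostate' and 'uterus'",
              "phenoval_bad_config")
  }
  models <- c("true_event", "history", "mimic", "testonly", "ruleout")
  missing_m <- setdiff(models, names(imaging_offset_models))
  if (length(missing_m)) {
    phv_abort(sprintf("`imaging_offset_models` missing: %s",
                      paste(missing_m, collapse = ", ")), "phenoval_bad_config")
  }
  imaging_offset_models <- lapply(stats::setNames(models, models), function(m)
    check_offset_model(imaging_offset_models[[m]], m))
  structure(list(
    n_patients = as.integer(n_patients),
    duplicate_patient_count = as.integer(duplicate_patient_count),
    invalid_date_count = as.integer(invalid_date_count),
    female_fraction = female_fraction, age_mean = age_mean, age_sd = age_sd,
    cancer_type_weights = cancer_type_weights, stage_weights = stage_weights,
    true_event_rate = true_event_rate,
    history_coding_rate = history_coding_rate,
    mimic_rate = mimic_rate,
    testonly_coding_rate = testonly_coding_rate,
    ruleout_suspected_rate = ruleout_suspected_rate,
    ruleout_true_prob = ruleout_true_prob,
    imaging_offset_models = imaging_offset_models,
    background_imaging_rate = background_imaging_rate,
    same_day_duplication_prob = same_day_duplication_prob,
    comorbidity_rates = comorbidity_rates,
    death_rate = death_rate,
    seed = seed), class = "synthetic_config")
}

uniform_dates_from <- function(from, to) {
  span <- as.integer(to - from) + 1L
  from + (floor(stats::runif(length(from)) * span))
}

generate_patients <- function(config) {
  n <- config$n_patients
  win <- study_window()
  local_seed(config$seed + 1L, {
    reg <- uniform_dates_from(rep(win[1], n), win[2])
    age <- pmax(1, stats::rnorm(n, config$age_mean, config$age_sd))
    sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
    w <- config$cancer_type_weights
    types <- character(n)
    f <- sex == "female"
    wf <- w[names(w) != "prostate"]
    wm <- w[names(w) != "uterus"]
    types[f] <- sample(names(wf), sum(f), TRUE, prob = wf)
    types[!f] <- sample(names(wm), sum(!f), TRUE, prob = wm)
    stage <- sample(names(config$stage_weights), n, TRUE, prob = config$stage_weights)
    dead <- stats::runif(n) < config$death_rate
    death <- as.Date(rep(NA_character_, n))
    death[dead] <- reg[dead] + sample.int(3000L, sum(dead), TRUE)
    data.frame(patient_id = sprintf("P%06d", seq_len(n)),
               birth_date = reg - as.integer(round(age * 365.25)),
               death_date = death, sex = sex, cancer_type = types,
               cancer_stage = stage, registration_date = reg,
               stringsAsFactors = FALSE)
  })
}

COMORBIDITY_CODES <- list(hypertension = c("I10", "I110", "I129", "I150"),
                          diabetes = c("E109", "E119", "E149"),
                          dyslipidemia = "E785",
                          atrial_fibrillation = "I48",
                          brain_metastases = "C793")

generate_comorbidities <- function(config, patients) {
  win <- study_window()
  local_seed(config$seed + 2L, {
    rows <- lapply(names(config$comorbidity_rates), function(nm) {
      idx <- which(stats::runif(nrow(patients)) < config$comorbidity_rates[[nm]])
      if (!length(idx)) return(NULL)
      pool <- COMORBIDITY_CODES[[nm]] %||% nm
      data.frame(patient_id = patients$patient_id[idx],
                 code = sample(pool, length(idx), TRUE),
                 registration_date = uniform_dates_from(
                   patients$registration_date[idx], win[2]),
                 certainty = "definite", position = "other",
                 department = "oncology", stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

sample_mimic_subtypes <- function(k) {
  sample(MIMIC_SUBTYPES, k, TRUE, prob = MIMIC_SUBTYPE_WEIGHTS)
}

generate_mechanism <- function(config, patients, mechanism, sub_seed) {
  rate <- switch(mechanism,
                 true_event = config$true_event_rate,
                 history = config$history_coding_rate,
                 mimic = config$mimic_rate,
                 testonly = config$testonly_coding_rate,
                 ruleout = config$ruleout_suspected_rate)
  model <- config$imaging_offset_models[[mechanism]]
  win <- study_window()
  local_seed(sub_seed, {
    idx <- which(stats::runif(nrow(patients)) < rate)
    k <- length(idx)
    if (k == 0L) return(NULL)
    date <- uniform_dates_from(patients$registration_date[idx], win[2])
    has_img <- stats::runif(k) >= model$p_none
    offset <- rep(NA_integer_, k)
    if (any(has_img)) {
      offset[has_img] <- sample(model$offsets, sum(has_img), TRUE, prob = model$probs)
    }
    if (mechanism == "ruleout") {
      truth <- ifelse(stats::runif(k) < config$ruleout_true_prob,
                      "acute_cvd", "not_acute_cvd")
      category <- rep(NA_character_, k)
      neg <- truth == "not_acute_cvd"
      category[neg] <- sample(NONDISEASE_CATEGORIES, sum(neg), TRUE,
                              prob = c(0.2, 0.6, 0.2))
    } else if (mechanism == "true_event") {
      truth <- rep("acute_cvd", k)
      category <- rep(NA_character_, k)
    } else {
      truth <- rep("not_acute_cvd", k)
      category <- rep(switch(mechanism,
                             history = "history_of_stroke",
                             mimic = "stroke_mimic",
                             testonly = "blood_or_imaging_tests"), k)
    }
    subtype <- rep(NA_character_, k)
    is_mimic_cat <- !is.na(category) & category == "stroke_mimic"
    if (any(is_mimic_cat)) subtype[is_mimic_cat] <- sample_mimic_subtypes(sum(is_mimic_cat))
    data.frame(patient_id = patients$patient_id[idx],
               code = sample(STROKE_CODE_POOL, k, TRUE, prob = STROKE_CODE_WEIGHTS),
               registration_date = date,
               certainty = if (mechanism == "ruleout") "suspected" else "definite",
               position = sample(names(POSITION_PROBS), k, TRUE, prob = POSITION_PROBS),
               department = "neurology",
               mechanism = mechanism, truth = truth, category = category,
               mimic_subtype = subtype, img_offset = offset,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic EMR bundle with latent ground truth
#'
#' Emits a full [emr_bundle()] (registry with optional pre-cleaning
#' duplicate/invalid rows, diagnosis registrations including same-day
#' duplicates and covariate codes, imaging orders) together with a truth
#' table covering every stroke-code record. Reproducible: the same config
#' (including seed) always yields the identical bundle. Sub-streams are
#' seeded per table and per mechanism.
#'
#' @param config a [synthetic_config()].
#' @return List with `bundle` (an [emr_bundle()]) and `truth` (data frame
#'   `record_id`, `truth`, `category`, `mimic_subtype`, `mechanism`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  win <- study_window()
  patients <- generate_patients(config)
  comorbid <- generate_comorbidities(config, patients)

  mech_seeds <- c(true_event = 11L, history = 12L, mimic = 13L,
                  testonly = 14L, ruleout = 15L)
  events <- do.call(rbind, Filter(Negate(is.null), lapply(
    names(mech_seeds), function(m)
      generate_mechanism(config, patients, m, config$seed + mech_seeds[[m]]))))

  # same-day re-registrations by other departments
  extras <- NULL
  if (!is.null(events) && nrow(events)) {
    extras <- local_seed(config$seed + 20L, {
      p <- unname(config$same_day_duplication_prob[events$certainty])
      n_extra <- stats::rgeom(nrow(events), prob = 1 - p)
      rep_idx <- rep(seq_len(nrow(events)), n_extra)
      if (!length(rep_idx)) return(NULL)
      e <- events[rep_idx, , drop = FALSE]
      e$position <- sample(names(POSITION_PROBS), nrow(e), TRUE,
                           prob = c(0.05, 0.45, 0.50))
      e$department <- "second_department"
      e
    })
  }

  stroke <- rbind(events, extras)
  diag_cols <- c("patient_id", "code", "registration_date", "certainty",
                 "position", "department")
  diagnoses <- rbind(
    if (!is.null(comorbid)) comorbid[diag_cols] else NULL,
    if (!is.null(stroke)) stroke[diag_cols] else NULL)
  if (is.null(diagnoses)) {
    diagnoses <- data.frame(patient_id = character(), code = character(),
                            registration_date = as.Date(character()),
                            certainty = character(), position = character(),
                            department = character(), stringsAsFactors = FALSE)
  }
  diagnoses <- cbind(record_id = sprintf("D%07d", seq_len(nrow(diagnoses))),
                     diagnoses, stringsAsFactors = FALSE)

  n_comorbid <- if (is.null(comorbid)) 0L else nrow(comorbid)
  truth <- if (is.null(stroke) || !nrow(stroke)) {
    data.frame(record_id = character(), truth = character(),
               category = character(), mimic_subtype = character(),
               mechanism = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(record_id = diagnoses$record_id[n_comorbid + seq_len(nrow(stroke))],
               truth = stroke$truth, category = stroke$category,
               mimic_subtype = stroke$mimic_subtype,
               mechanism = stroke$mechanism, stringsAsFactors = FALSE)
  }

  # mechanism-linked imaging orders
  proc_rows <- NULL
  if (!is.null(events) && any(!is.na(events$img_offset))) {
    with_img <- events[!is.na(events$img_offset), , drop = FALSE]
    proc_rows <- data.frame(patient_id = with_img$patient_id,
                            order_date = with_img$registration_date + with_img$img_offset,
                            stringsAsFactors = FALSE)
  }
  # background imaging: brain-tumour surveillance plus a small random fraction
  bg <- local_seed(config$seed + 21L, {
    brain <- patients$patient_id[patients$cancer_type == "brain"]
    other <- patients[patients$cancer_type != "brain", , drop = FALSE]
    other <- other[stats::runif(nrow(other)) < config$background_imaging_rate, ,
                   drop = FALSE]
    ids <- c(rep(brain, 2L), other$patient_id)
    if (!length(ids)) return(NULL)
    reg <- patients$registration_date[match(ids, patients$patient_id)]
    data.frame(patient_id = ids,
               order_date = uniform_dates_from(reg, win[2]),
               stringsAsFactors = FALSE)
  })
  procedures <- rbind(proc_rows, bg)
  if (is.null(procedures)) {
    procedures <- data.frame(patient_id = character(),
                             order_date = as.Date(character()),
                             stringsAsFactors = FALSE)
  }
  procedures <- data.frame(record_id = sprintf("R%07d", seq_len(nrow(procedures))),
                           patient_id = procedures$patient_id,
                           modality = if (nrow(procedures))
                             rep_len(c("MRI", "CT"), nrow(procedures)) else character(),
                           order_date = procedures$order_date,
                           stringsAsFactors = FALSE)

  # pre-cleaning injections: repeat registrations and impossible dates
  registry <- local_seed(config$seed + 22L, {
    extra <- NULL
    if (config$duplicate_patient_count > 0L) {
      idx <- sample.int(nrow(patients), config$duplicate_patient_count, TRUE)
      dup <- patients[idx, , drop = FALSE]
      dup$registration_date <- dup$registration_date +
        sample.int(365L, nrow(dup), TRUE)
      extra <- dup
    }
    if (config$invalid_date_count > 0L) {
      k <- config$invalid_date_count
      birth <- as.Date("1950-01-01") + seq_len(k) * 100L
      bad <- data.frame(patient_id = sprintf("PX%05d", seq_len(k)),
                        birth_date = birth, death_date = birth - 10L,
                        sex = rep_len(c("male", "female"), k),
                        cancer_type = "others", cancer_stage = "unknown",
                        registration_date = uniform_dates_from(
                          rep(win[1], k), win[2]),
                        stringsAsFactors = FALSE)
      extra <- rbind(extra, bad)
    }
    rbind(patients, extra)
  })
  rownames(registry) <- rownames(diagnoses) <- rownames(procedures) <- NULL
  list(bundle = emr_bundle(registry, diagnoses, procedures), truth = truth)
}

#' Simulate chart review from the latent truth
#'
#' Copies the generator's truth labels onto a review sample — a perfect
#' reviewer — optionally flipping each truth with probability `noise` to
#' study the estimate's robustness to reviewer error.
#'
#' @param sample sampled records (with `record_id`).
#' @param truth_table the `truth` element of [generate_cohort()] /
#'   [generate_fixture()].
#' @param noise per-record flip probability (default 0).
#' @param seed required when `noise > 0`.
#' @return Label data frame `record_id`, `truth`, `category`, `mimic_subtype`.
#' @export
auto_label <- function(sample, truth_table, noise = 0, seed = NULL) {
  check_prob(noise, "noise")
  pos <- match(sample$record_id, truth_table$record_id)
  if (anyNA(pos)) {
    phv_abort(sprintf("sampled record(s) missing from the truth table: %s",
                      paste(utils::head(sample$record_id[is.na(pos)], 10L),
                            collapse = ", ")),
              "phenoval_missing_truth")
  }
  out <- truth_table[pos, c("record_id", "truth", "category", "mimic_subtype"),
                     drop = FALSE]
  rownames(out) <- NULL
  if (noise > 0) {
    if (is.null(seed)) {
      phv_abort("`seed` is required when `noise` > 0", "phenoval_bad_config")
    }
    flip <- local_seed(check_seed(seed), stats::runif(nrow(out)) < noise)
    was_pos <- out$truth == "acute_cvd"
    out$truth[flip & was_pos] <- "not_acute_cvd"
    out$category[flip & was_pos] <- "stroke_mimic"
    out$mimic_subtype[flip & was_pos] <- NA_character_
    out$truth[flip & !was_pos] <- "acute_cvd"
    out$category[flip & !was_pos] <- NA_character_
    out$mimic_subtype[flip & !was_pos] <- NA_character_
  }
  out
}

#' Realized truth fraction of one arm
#'
#' The generator-side analogue of the PPV: the fraction of all records in
#' the arm whose latent truth is acute cerebrovascular disease.
#'
#' @param assignments a [classify_arms()] result.
#' @param truth_table truth table covering the records.
#' @param arm arm name.
#' @return Proportion in `[0, 1]`.
#' @export
arm_truth_fraction <- function(assignments, truth_table, arm) {
  recs <- arm_records(assignments, arm)
  pos <- match(recs$record_id, truth_table$record_id)
  if (anyNA(pos)) {
    phv_abort("arm records missing from the truth table", "phenoval_missing_truth")
  }
  mean(truth_table$truth[pos] == "acute_cvd")
}

#' Run the full phenotyping pipeline on a bundle
#'
#' Registry cleaning, stroke-code extraction restricted to the retained
#' cohort, same-day deduplication, and arm classification.
#'
#' @param bundle an [emr_bundle()].
#' @param set the [code_set()] to extract (default the stroke set).
#' @param arm_specs arm definitions (default the five shipped arms).
#' @return List: `clean` ([clean_registry()] result), `extracted`,
#'   `deduped`, `assignments` ([classify_arms()] result) and `counts`.
#' @export
run_pipeline <- function(bundle, set = stroke_code_set(),
                         arm_specs = default_arm_specs()) {
  clean <- clean_registry(bundle$patients)
  extracted <- extract_codes(bundle$diagnoses, set)
  extracted <- extracted[extracted$patient_id %in% clean$retained$patient_id, ,
                         drop = FALSE]
  deduped <- dedup_diagnoses(extracted)
  assignments <- classify_arms(deduped, bundle$procedures, arm_specs)
  list(clean = clean, extracted = extracted, deduped = deduped,
       assignments = assignments, counts = arm_counts(assignments))
}

#' Load a generator scenario from YAML
#'
#' @param path YAML file whose keys are [synthetic_config()] arguments; a
#'   `seed` entry in the file is overridden by the `seed` argument when
#'   supplied.
#' @param seed optional seed override.
#' @return A [synthetic_config()].
#' @export
read_scenario <- function(path, seed = NULL) {
  args <- yaml::read_yaml(path)
  for (nm in c("cancer_type_weights", "stage_weights", "comorbidity_rates",
               "same_day_duplication_prob")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  if (!is.null(args$imaging_offset_models)) {
    args$imaging_offset_models <- lapply(args$imaging_offset_models, function(m) {
      m$offsets <- unlist(m$offsets); m$probs <- unlist(m$probs); m
    })
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(synthetic_config, args)
}
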