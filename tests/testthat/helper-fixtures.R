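# Builders and brute-force oracles shared across test files.

d <- function(x) as.Date(x)

make_patients <- function(ids, reg = "2010-01-01", birth = "1950-01-01",
                          death = NA_character_) {
  n <- length(ids)
  data.frame(patient_id = ids,
             birth_date = d(rep_len(birth, n)),
             death_date = d(rep_len(death, n)),
             sex = rep_len(c("female", "male"), n),
             cancer_type = rep_len("others", n),
             cancer_stage = rep_len("unknown", n),
             registration_date = d(rep_len(reg, n)),
             stringsAsFactors = FALSE)
}

make_diagnoses <- function(patient_id, code = "I639", date = "2010-06-01",
                           certainty = "definite", position = "secondary",
                           record_id = NULL) {
  n <- length(patient_id)
  data.frame(record_id = record_id %||% sprintf("D%03d", seq_len(n)),
             patient_id = patient_id,
             code = rep_len(code, n),
             registration_date = d(rep_len(date, n)),
             certainty = rep_len(certainty, n),
             position = rep_len(position, n),
             department = rep_len(NA_character_, n),
             stringsAsFactors = FALSE)
}

make_procedures <- function(patient_id, date, modality = "MRI") {
  n <- length(patient_id)
  data.frame(record_id = sprintf("R%03d", seq_len(n)),
             patient_id = patient_id,
             modality = rep_len(modality, n),
             order_date = d(rep_len(date, n)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small diagnosis/procedure tables for property tests
random_tables <- function(seed, n_rec = 60, n_proc = 40, n_pat = 10) {
  set.seed(seed)
  base <- d("2010-01-01")
  pats <- sprintf("P%02d", seq_len(n_pat))
  records <- data.frame(
    record_id = sprintf("D%03d", seq_len(n_rec)),
    patient_id = sample(pats, n_rec, TRUE),
    code = sample(c("I639", "I619", "G458"), n_rec, TRUE),
    registration_date = base + sample.int(90L, n_rec, TRUE),
    certainty = sample(c("definite", "suspected"), n_rec, TRUE),
    position = sample(c("primary", "secondary", "other"), n_rec, TRUE),
    department = NA_character_, stringsAsFactors = FALSE)
  procedures <- data.frame(
    record_id = sprintf("R%03d", seq_len(n_proc)),
    patient_id = sample(pats, n_proc, TRUE),
    modality = sample(c("CT", "MRI"), n_proc, TRUE),
    order_date = base + sample.int(150L, n_proc, TRUE) - 30L,
    stringsAsFactors = FALSE)
  list(records = records, procedures = procedures)
}

# brute-force arm membership: scan every procedure for every record
oracle_arm_member <- function(rec, procedures, spec) {
  if (rec$certainty != spec$certainty) return(FALSE)
  offs <- as.integer(procedures$order_date[procedures$patient_id == rec$patient_id] -
                       rec$registration_date)
  switch(spec$imaging,
         not_required = TRUE,
         any = length(offs) > 0L,
         within_days = switch(spec$direction,
                              two_sided = any(abs(offs) <= spec$window),
                              after_only = any(offs >= 0L & offs <= spec$window),
                              before_only = any(offs <= 0L & -offs <= spec$window)))
}

# brute-force nearest offset: enumerate all pairs, smallest |offset|,
# non-negative wins ties
oracle_nearest_offset <- function(rec, procedures) {
  offs <- as.integer(procedures$order_date[procedures$patient_id == rec$patient_id] -
                       rec$registration_date)
  if (!length(offs)) return(NA_integer_)
  best <- offs[order(abs(offs), offs < 0L)][1L]
  best
}

# brute-force range membership: enumerate every category in each range
oracle_match_code <- function(code, set) {
  category <- substr(code, 1L, 3L)
  if (code %in% set$exact_codes) return(TRUE)
  if (category %in% set$category_prefixes) return(TRUE)
  for (r in set$category_ranges) {
    letter <- substr(r[1], 1L, 1L)
    lo <- as.integer(substr(r[1], 2L, 3L))
    hi <- as.integer(substr(r[2], 2L, 3L))
    cats <- sprintf("%s%02d", letter, lo:hi)
    if (category %in% cats) return(TRUE)
  }
  FALSE
}

recovery_config <- function(seed) {
  synthetic_config(n_patients = 2500L,
                   true_event_rate = 0.0624,
                   history_coding_rate = 0.116,
                   mimic_rate = 0.0624,
                   testonly_coding_rate = 0.0424,
                   ruleout_suspected_rate = 0.0704,
                   same_day_duplication_prob = c(definite = 0.3, suspected = 0.3),
                   seed = seed)
}
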