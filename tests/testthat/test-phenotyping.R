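test_that("same-day duplicates collapse to the highest-position record", {
  recs <- make_diagnoses(c("P01", "P01"), position = c("secondary", "primary"))
  out <- dedup_diagnoses(recs)
  expect_identical(nrow(out), 1L)
  expect_identical(out$position, "primary")
  # adjacent days are distinct events, not duplicates
  recs2 <- make_diagnoses(c("P01", "P01"), date = c("2010-06-01", "2010-06-02"))
  expect_identical(nrow(dedup_diagnoses(recs2)), 2L)
  # definite and suspected registrations deduplicate independently
  recs3 <- make_diagnoses(c("P01", "P01"), certainty = c("definite", "suspected"))
  expect_identical(nrow(dedup_diagnoses(recs3)), 2L)
  # position tie resolves by record order
  recs4 <- make_diagnoses(c("P01", "P01"), position = "other")
  expect_identical(dedup_diagnoses(recs4)$record_id, "D001")
})

test_that("dedup is idempotent, never grows, and its size ignores row order", {
  for (seed in 1:8) {
    tabs <- random_tables(seed)
    once <- dedup_diagnoses(tabs$records)
    expect_lte(nrow(once), nrow(tabs$records))
    expect_identical(dedup_diagnoses(once), once)
    perm <- dedup_diagnoses(tabs$records[sample.int(nrow(tabs$records)), ])
    expect_identical(nrow(perm), nrow(once))
  }
})

test_that("nearest offset picks the smallest absolute day difference, non-negative on ties", {
  rec <- make_diagnoses("P01", date = "2010-06-01")[1, ]
  expect_identical(nearest_imaging_offset(rec, make_procedures(c("P01", "P01"),
                                                               c("2010-05-27", "2010-06-03"))), 2L)
  expect_identical(nearest_imaging_offset(rec, make_procedures(c("P01", "P01"),
                                                               c("2010-05-31", "2010-06-02"))), 1L)
  expect_identical(nearest_imaging_offset(rec, make_procedures("P02", "2010-06-01")),
                   NA_integer_)
  # agreement with the all-pairs oracle on random tables
  for (seed in 11:16) {
    tabs <- random_tables(seed)
    for (i in seq_len(nrow(tabs$records))) {
      expect_identical(nearest_imaging_offset(tabs$records[i, ], tabs$procedures),
                       oracle_nearest_offset(tabs$records[i, ], tabs$procedures))
    }
  }
})

test_that("window boundaries are inclusive and two-sided by default", {
  rec <- make_diagnoses("P01", date = "2010-06-01")
  asg31 <- classify_arms(rec, make_procedures("P01", "2010-07-02"))  # +31 days
  expect_true(asg31$definite & asg31$definite_any_imaging)
  expect_false(asg31$definite_imaging_30d)
  asg30 <- classify_arms(rec, make_procedures("P01", "2010-07-01"))  # +30 days
  expect_true(asg30$definite_imaging_30d)
  asg_m1 <- classify_arms(rec, make_procedures("P01", "2010-05-31"))  # -1 day
  expect_true(asg_m1$definite_imaging_1d)
  # after_only direction excludes imaging strictly before the code date
  after <- default_arm_specs(direction = "after_only")
  expect_false(classify_arms(rec, make_procedures("P01", "2010-05-31"),
                             after)$definite_imaging_1d)
  expect_true(classify_arms(rec, make_procedures("P01", "2010-06-02"),
                            after)$definite_imaging_1d)
})

test_that("arm classification matches the brute-force all-pairs oracle", {
  specs <- c(default_arm_specs(),
             list(after_w7 = arm_spec("after_w7", "definite", "within_days", 7L, "after_only"),
                  before_w7 = arm_spec("before_w7", "suspected", "within_days", 7L, "before_only")))
  for (seed in 21:28) {
    tabs <- random_tables(seed, n_rec = 120, n_proc = 80, n_pat = 15)
    deduped <- dedup_diagnoses(tabs$records)
    asg <- classify_arms(deduped, tabs$procedures, specs)
    for (spec in specs) {
      want <- vapply(seq_len(nrow(deduped)), function(i)
        oracle_arm_member(deduped[i, ], tabs$procedures, spec), logical(1))
      expect_identical(asg[[spec$name]], want)
    }
    expect_identical(asg$nearest_offset,
                     vapply(seq_len(nrow(deduped)), function(i)
                       oracle_nearest_offset(deduped[i, ], tabs$procedures), integer(1)))
  }
})

test_that("arm counts nest and ignore input row order", {
  for (seed in 31:38) {
    tabs <- random_tables(seed, n_rec = 150, n_proc = 60, n_pat = 12)
    deduped <- dedup_diagnoses(tabs$records)
    counts <- arm_counts(classify_arms(deduped, tabs$procedures))
    expect_lte(counts[["definite_imaging_1d"]], counts[["definite_imaging_30d"]])
    expect_lte(counts[["definite_imaging_30d"]], counts[["definite_any_imaging"]])
    expect_lte(counts[["definite_any_imaging"]], counts[["definite"]])
    perm <- arm_counts(classify_arms(deduped[sample.int(nrow(deduped)), ],
                                     tabs$procedures[sample.int(nrow(tabs$procedures)), ]))
    expect_identical(counts, perm)
  }
  empty <- classify_arms(make_diagnoses(character()),
                         make_procedures(character(), character()))
  expect_identical(unname(arm_counts(empty)), rep(0L, 5L))
})

test_that("unknown arm names are rejected", {
  tabs <- random_tables(41)
  asg <- classify_arms(dedup_diagnoses(tabs$records), tabs$procedures)
  expect_error(arm_records(asg, "no_such_arm"), class = "phenoval_unknown_arm")
})
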