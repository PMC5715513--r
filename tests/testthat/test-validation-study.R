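test_that("review sampling is uniform without replacement, seeded and warns when short", {
  tabs <- random_tables(51, n_rec = 300, n_pat = 60)
  recs <- dedup_diagnoses(tabs$records)
  s1 <- draw_review_sample(recs, 100L, seed = 7L)
  s2 <- draw_review_sample(recs, 100L, seed = 7L)
  expect_identical(s1$record_id, s2$record_id)
  expect_identical(length(unique(s1$record_id)), 100L)
  # different seeds give different samples (collision is astronomically unlikely)
  for (seeds in list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(8L, 9L), c(10L, 11L))) {
    expect_false(identical(draw_review_sample(recs, 100L, seeds[1])$record_id,
                           draw_review_sample(recs, 100L, seeds[2])$record_id))
  }
  small <- recs[1:50, ]
  expect_warning(all50 <- draw_review_sample(small, 100L, seed = 1L),
                 class = "phenoval_undersized_sample")
  expect_identical(sort(all50$record_id), sort(small$record_id))
  expect_error(draw_review_sample(recs[0, ], 100L, seed = 1L),
               class = "phenoval_empty_arm")
})

test_that("ppv estimates carry exact binomial intervals matching binom.test", {
  for (case in list(c(0L, 100L), c(22L, 100L), c(84L, 93L), c(4L, 7L), c(92L, 92L))) {
    est <- ppv_estimate(case[1], case[2])
    expect_identical(est$ppv, case[1] / case[2])
    if (case[1] == 0L) expect_identical(est$ci_low, 0)
    if (case[1] == case[2]) expect_identical(est$ci_high, 1)
    oracle <- stats::binom.test(case[1], case[2])$conf.int
    expect_equal(est$ci_low, oracle[1], tolerance = 1e-12)
    expect_equal(est$ci_high, oracle[2], tolerance = 1e-12)
    expect_true(est$ci_low <= est$ppv && est$ppv <= est$ci_high)
  }
  w <- ppv_estimate(9L, 10L, method = "wilson")
  expect_lt(w$ci_high, 1)
  expect_error(ppv_estimate(5L, 4L), class = "phenoval_bad_config")
})

test_that("position strata estimate from labels and fail loudly on missing labels", {
  sample <- make_diagnoses(sprintf("P%02d", 1:10),
                           position = c(rep("primary", 3), rep("secondary", 4),
                                        rep("other", 3)))
  labels <- data.frame(record_id = sample$record_id,
                       truth = c("acute_cvd", "acute_cvd", "not_acute_cvd",
                                 rep("not_acute_cvd", 6), "acute_cvd"),
                       category = NA_character_, mimic_subtype = NA_character_,
                       stringsAsFactors = FALSE)
  labels$category[labels$truth == "not_acute_cvd"] <- "history_of_stroke"
  all <- estimate_ppv(sample, labels, "all")
  prim <- estimate_ppv(sample, labels, "primary")
  sec <- estimate_ppv(sample, labels, "secondary_or_others")
  expect_identical(all$n_positive, 3L)
  expect_identical(prim$n_sampled, 3L)
  expect_identical(sec$n_sampled, 7L)
  expect_identical(prim$n_positive + sec$n_positive, all$n_positive)
  err <- expect_error(estimate_ppv(sample, labels[-2, ], "all"),
                      class = "phenoval_missing_labels")
  expect_match(conditionMessage(err), sample$record_id[2])
})

test_that("pooling sums counts exactly and equals the weighted mean of strata", {
  pool <- pooled_ppv(list(ppv_estimate(4L, 7L, "primary"),
                          ppv_estimate(18L, 93L, "secondary_or_others")))
  expect_identical(pool$n_positive, 22L)
  expect_identical(pool$n_sampled, 100L)
  expect_identical(pool$report_percent, 22L)
  set.seed(99)
  for (i in 1:20) {
    n1 <- sample.int(80L, 1L); n2 <- sample.int(80L, 1L)
    k1 <- sample.int(n1, 1L); k2 <- sample.int(n2, 1L)
    pool <- pooled_ppv(list(ppv_estimate(k1, n1, "primary"),
                            ppv_estimate(k2, n2, "secondary_or_others")))
    expect_equal(pool$ppv, (n1 * (k1 / n1) + n2 * (k2 / n2)) / (n1 + n2),
                 tolerance = 1e-12)
  }
  expect_identical(pooled_ppv(list(ppv_estimate(5L, 10L, "all")))$n_sampled, 10L)
  expect_error(pooled_ppv(list(ppv_estimate(1L, 2L, "primary"),
                               ppv_estimate(1L, 2L, "primary"))),
               class = "phenoval_overlapping_strata")
})

test_that("non-disease tallies partition the negative labels", {
  labels <- data.frame(
    record_id = sprintf("D%03d", 1:100),
    truth = c(rep("acute_cvd", 22), rep("not_acute_cvd", 78)),
    category = c(rep(NA_character_, 22), rep("history_of_stroke", 41),
                 rep("stroke_mimic", 22), rep("blood_or_imaging_tests", 15)),
    mimic_subtype = NA_character_, stringsAsFactors = FALSE)
  labels$mimic_subtype[labels$category %in% "stroke_mimic"] <-
    rep_len(c("seizure", "syncope"), 22)
  t <- tally_nondisease(labels)
  expect_identical(unname(unclass(t)[1:3]), c(41L, 22L, 15L))
  expect_identical(attr(t, "total"), 78L)
  expect_identical(sum(attr(t, "mimic_subtypes")), 22L)
  none <- tally_nondisease(labels[labels$truth == "acute_cvd", ])
  expect_identical(attr(none, "total"), 0L)
  # property: tally total always equals the non-positive count
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200L
    lab <- data.frame(record_id = sprintf("D%03d", 1:n),
                      truth = sample(c("acute_cvd", "not_acute_cvd"), n, TRUE),
                      category = NA_character_, mimic_subtype = NA_character_,
                      stringsAsFactors = FALSE)
    neg <- lab$truth == "not_acute_cvd"
    lab$category[neg] <- sample(c("history_of_stroke", "stroke_mimic",
                                  "blood_or_imaging_tests"), sum(neg), TRUE)
    expect_identical(sum(unclass(tally_nondisease(lab))), sum(neg))
  }
})

test_that("reports are deterministic and degrade to arm counts without labels", {
  fx <- generate_fixture(fixture_spec(registry_rows = 600, duplicate_rows = 20,
                                      invalid_date_rows = 5, distinct_definite = 150,
                                      total_definite = 300, distinct_suspected = 40,
                                      total_suspected = 80, n_any_imaging = 90,
                                      n_within_30 = 60, n_within_1 = 40, seed = 3L))
  res <- run_pipeline(fx$bundle)
  labels <- auto_label(res$deduped, fx$truth)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  p1 <- render_report(res$assignments, labels, dir1, sample_size = 50L, seed = 5L)
  p2 <- render_report(res$assignments, labels, dir2, sample_size = 50L, seed = 5L)
  expect_true(all(file.exists(p1)))
  for (i in seq_along(p1)) expect_identical(readLines(p1[i]), readLines(p2[i]))
  expect_true(any(grepl("ppv_by_arm", p1)))
  bare <- render_report(res$assignments, NULL, withr::local_tempdir(), seed = 5L)
  expect_false(any(grepl("ppv_by_arm", bare)))
  expect_true(any(grepl("arm_counts", bare)))
})
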