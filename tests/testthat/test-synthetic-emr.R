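test_that("generation is reproducible and every stroke record has a truth label", {
  cfg <- synthetic_config(n_patients = 800L, seed = 5L)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$bundle$patients, g2$bundle$patients)
  expect_identical(g1$bundle$diagnoses, g2$bundle$diagnoses)
  expect_identical(g1$bundle$procedures, g2$bundle$procedures)
  expect_identical(g1$truth, g2$truth)
  stroke_ids <- extract_codes(g1$bundle$diagnoses, stroke_code_set())$record_id
  expect_setequal(g1$truth$record_id, stroke_ids)
  # non-disease records always carry a category; positives never do
  neg <- g1$truth$truth == "not_acute_cvd"
  expect_true(all(g1$truth$category[neg] %in%
                    c("history_of_stroke", "stroke_mimic", "blood_or_imaging_tests")))
  expect_true(all(is.na(g1$truth$category[!neg])))
})

test_that("a pure true-event cohort with same-day imaging yields 100% PPV in every arm", {
  models <- default_offset_models()
  models$true_event <- list(p_none = 0, offsets = 0L, probs = 1)
  cfg <- synthetic_config(n_patients = 1500L,
                          true_event_rate = 0.05,
                          history_coding_rate = 0, mimic_rate = 0,
                          testonly_coding_rate = 0, ruleout_suspected_rate = 0,
                          imaging_offset_models = models,
                          background_imaging_rate = 0, seed = 9L)
  g <- generate_cohort(cfg)
  res <- run_pipeline(g$bundle)
  for (arm in c("definite", "definite_any_imaging", "definite_imaging_30d",
                "definite_imaging_1d")) {
    expect_identical(arm_truth_fraction(res$assignments, g$truth, arm), 1)
  }
  expect_identical(res$counts[["definite"]], res$counts[["definite_imaging_1d"]])
})

test_that("generated demographics match the configured moments", {
  cfg <- synthetic_config(seed = 13L)  # full scale, n = 25,827
  g <- generate_cohort(cfg)
  pats <- clean_registry(g$bundle$patients)$retained
  n <- nrow(pats)
  expect_identical(n, 25827L)
  f <- mean(pats$sex == "female")
  expect_lt(abs(f - 0.495), 3 * sqrt(0.495 * 0.505 / n))
  age <- as.numeric(pats$registration_date - pats$birth_date) / 365.25
  expect_lt(abs(mean(age) - 61.6), 3 * 15.7 / sqrt(n) + 0.01)
  expect_lt(abs(sd(age) - 15.7), 0.5)
  # sex-specific cancers are consistent
  expect_true(all(pats$sex[pats$cancer_type == "prostate"] == "male"))
  expect_true(all(pats$sex[pats$cancer_type == "uterus"] == "female"))
})

test_that("injected registry noise is recovered exactly by cleaning", {
  cfg <- synthetic_config(n_patients = 2000L, duplicate_patient_count = 150L,
                          invalid_date_count = 7L, seed = 21L)
  g <- generate_cohort(cfg)
  expect_identical(nrow(g$bundle$patients), 2157L)
  res <- clean_registry(g$bundle$patients)
  expect_identical(nrow(res$retained), 2000L)
  expect_identical(unname(exclusion_summary(res$log)), c(150L, 7L))
})

test_that("arm PPV concentrates around the configured truth fraction", {
  # with only true events and rule-outs, the within-1-day arm truth fraction
  # is governed by ruleout_true_prob in the suspected arm and 1 in definite
  cfg <- recovery_config(31L)
  g <- generate_cohort(cfg)
  res <- run_pipeline(g$bundle)
  p_hat <- arm_truth_fraction(res$assignments, g$truth, "suspected_any_imaging")
  n_arm <- res$counts[["suspected_any_imaging"]]
  expect_lt(abs(p_hat - 0.07), 3 * sqrt(0.07 * 0.93 / n_arm))
})

test_that("raising the test-only coding rate dilutes the definite arm but not the within-1-day arm", {
  for (seed in c(41L, 42L, 43L)) {
    lo <- recovery_config(seed)
    hi <- recovery_config(seed)
    hi$testonly_coding_rate <- 0.20
    g_lo <- generate_cohort(lo); g_hi <- generate_cohort(hi)
    r_lo <- run_pipeline(g_lo$bundle); r_hi <- run_pipeline(g_hi$bundle)
    expect_lt(arm_truth_fraction(r_hi$assignments, g_hi$truth, "definite"),
              arm_truth_fraction(r_lo$assignments, g_lo$truth, "definite"))
    # per-mechanism sub-streams: the other mechanisms' draws are untouched,
    # so the within-1-day arm shifts only via rare background-imaging overlap
    expect_lt(abs(arm_truth_fraction(r_hi$assignments, g_hi$truth, "definite_imaging_1d") -
                    arm_truth_fraction(r_lo$assignments, g_lo$truth, "definite_imaging_1d")),
              0.02)
  }
})

test_that("auto labelling copies latent truth and flips at the configured noise rate", {
  fx <- generate_fixture(fixture_spec(registry_rows = 1500, duplicate_rows = 0,
                                      invalid_date_rows = 0, distinct_definite = 1000,
                                      total_definite = 1200, distinct_suspected = 100,
                                      total_suspected = 100, n_any_imaging = 600,
                                      n_within_30 = 400, n_within_1 = 200, seed = 2L))
  res <- run_pipeline(fx$bundle)
  sample <- res$deduped
  clean_lab <- auto_label(sample, fx$truth)
  expect_identical(clean_lab$truth,
                   fx$truth$truth[match(sample$record_id, fx$truth$record_id)])
  flipped <- auto_label(sample, fx$truth, noise = 1, seed = 1L)
  expect_true(all(flipped$truth != clean_lab$truth))
  noisy <- auto_label(sample, fx$truth, noise = 0.1, seed = 1L)
  n_flip <- sum(noisy$truth != clean_lab$truth)
  n <- nrow(sample)
  expect_lt(abs(n_flip - 0.1 * n), 3 * sqrt(0.1 * 0.9 * n))
  expect_error(auto_label(make_diagnoses("P01", record_id = "ZZZ"), fx$truth),
               class = "phenoval_missing_truth")
})

test_that("infeasible fixture specifications are rejected by name", {
  expect_error(fixture_spec(n_within_1 = 300, n_within_30 = 200),
               class = "phenoval_infeasible_fixture")
  expect_error(fixture_spec(n_any_imaging = 1000),
               class = "phenoval_infeasible_fixture")
  expect_error(fixture_spec(total_definite = 500),
               class = "phenoval_infeasible_fixture")
  expect_error(fixture_spec(registry_rows = 500),
               class = "phenoval_infeasible_fixture")
  # totals equal to distincts make dedup a no-op
  fx <- generate_fixture(fixture_spec(registry_rows = 400, duplicate_rows = 0,
                                      invalid_date_rows = 0, distinct_definite = 100,
                                      total_definite = 100, distinct_suspected = 50,
                                      total_suspected = 50, n_any_imaging = 60,
                                      n_within_30 = 30, n_within_1 = 10, seed = 4L))
  expect_identical(nrow(dedup_diagnoses(fx$bundle$diagnoses)),
                   nrow(fx$bundle$diagnoses))
})

test_that("scenario and fixture YAML files round-trip through their readers", {
  scen <- read_scenario(system.file("extdata", "scenario_default.yaml",
                                    package = "phenoval"), seed = 77L)
  expect_s3_class(scen, "synthetic_config")
  expect_identical(scen$n_patients, 25827L)
  expect_identical(scen$seed, 77L)
  fs <- read_fixture_spec(system.file("extdata", "fixture_default.yaml",
                                      package = "phenoval"))
  expect_s3_class(fs, "fixture_spec")
  expect_identical(fs$distinct_definite, 912L)
})

test_that("invalid generator configurations are rejected by name", {
  expect_error(synthetic_config(seed = 1L, female_fraction = 1.2),
               class = "phenoval_bad_config")
  expect_error(synthetic_config(seed = 1L, true_event_rate = -0.1),
               class = "phenoval_bad_config")
  expect_error(synthetic_config(seed = 1L, same_day_duplication_prob = c(definite = 1)),
               class = "phenoval_bad_config")
  expect_error(synthetic_config(n_patients = 100L))  # seed is mandatory
})
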