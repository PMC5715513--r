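# Validation layer: seeded chart-review sampling per arm, PPV estimation
# with exact binomial confidence intervals (overall and by code position),
# and the non-disease breakdown report.

NONDISEASE_CATEGORIES <- c("history_of_stroke", "stroke_mimic",
                           "blood_or_imaging_tests")
PPV_STRATA <- c("all", "primary", "secondary_or_others")

# Clopper-Pearson via the closed-form beta quantiles; Wilson score as the
# configurable alternative.
binom_ci <- function(k, n, conf_level = 0.95,
                     method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  alpha <- 1 - conf_level
  if (method == "clopper-pearson") {
    low <- if (k == 0L) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    high <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    p <- k / n
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    low <- max(0, centre - half)
    high <- min(1, centre + half)
  }
  c(low = low, high = high)
}

#' Build a PPV estimate from review counts
#'
#' The positive predictive value of an algorithm arm is the fraction of
#' reviewed records confirmed as acute cerebrovascular disease. The exact
#' (Clopper-Pearson) interval is the default since arm PPVs near 0.9 at
#' n = 100 make normal approximations poor. `report_percent` is the
#' nearest-integer percent with ties rounded away from zero, matching how
#' such proportions are printed in validation tables.
#'
#' @param n_positive confirmed positives among the reviewed records.
#' @param n_sampled number of reviewed records (>= 1).
#' @param stratum `"all"`, `"primary"` or `"secondary_or_others"`.
#' @param conf_level confidence level (default 0.95).
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return Object of class `ppv_estimate` with fields `stratum`,
#'   `n_sampled`, `n_positive`, `ppv`, `ci_low`, `ci_high`,
#'   `report_percent`, `conf_level`, `method`.
#' @export
ppv_estimate <- function(n_positive, n_sampled, stratum = "all",
                         conf_level = 0.95,
                         method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (n_sampled < 1L || n_positive < 0L || n_positive > n_sampled) {
    phv_abort("need 0 <= n_positive <= n_sampled and n_sampled >= 1",
              "phenoval_bad_config")
  }
  ci <- binom_ci(n_positive, n_sampled, conf_level, method)
  structure(list(stratum = stratum,
                 n_sampled = as.integer(n_sampled),
                 n_positive = as.integer(n_positive),
                 ppv = n_positive / n_sampled,
                 ci_low = unname(ci["low"]),
                 ci_high = unname(ci["high"]),
                 report_percent = round_half_away(100 * n_positive / n_sampled),
                 conf_level = conf_level,
                 method = method),
            class = "ppv_estimate")
}

#' @export
print.ppv_estimate <- function(x, ...) {
  cat(sprintf("<ppv_estimate> %s: %d/%d = %d%% (%.0f%% CI %.3f-%.3f, %s)\n",
              x$stratum, x$n_positive, x$n_sampled, x$report_percent,
              100 * x$conf_level, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' Draw a seeded uniform review sample from an arm
#'
#' Sampling is uniform without replacement and fully reproducible from the
#' seed. When the arm holds fewer records than requested, all of them are
#' returned with a classed warning (`phenoval_undersized_sample`).
#'
#' @param arm_records records of one arm (e.g. from [arm_records()]).
#' @param sample_size target number of records to review (default 100).
#' @param seed integer RNG seed (mandatory; the caller's RNG state is
#'   preserved).
#' @return Sampled rows of `arm_records`, with the seed and requested size
#'   stored as attributes.
#' @export
draw_review_sample <- function(arm_records, sample_size = 100L, seed) {
  if (nrow(arm_records) == 0L) {
    phv_abort("cannot sample from an empty arm", "phenoval_empty_arm")
  }
  seed <- check_seed(seed)
  n <- min(sample_size, nrow(arm_records))
  if (n < sample_size) {
    phv_warn(sprintf("arm holds %d records (< requested %d); returning all",
                     nrow(arm_records), sample_size),
             "phenoval_undersized_sample")
  }
  idx <- local_seed(seed, sample.int(nrow(arm_records), n))
  out <- arm_records[idx, , drop = FALSE]
  attr(out, "seed") <- seed
  attr(out, "sample_size") <- sample_size
  out
}

join_labels <- function(sample, labels) {
  pos <- match(sample$record_id, labels$record_id)
  if (anyNA(pos)) {
    missing <- sample$record_id[is.na(pos)]
    phv_abort(sprintf("no review label for sampled record(s): %s",
                      paste(utils::head(missing, 10L), collapse = ", ")),
              "phenoval_missing_labels", record_ids = missing)
  }
  labels[pos, , drop = FALSE]
}

#' Estimate an arm's PPV from a review sample and its labels
#'
#' Joins the chart-review labels onto the sampled records (erroring with
#' the offending ids when any label is missing) and computes the PPV with
#' its exact binomial interval. The `primary` / `secondary_or_others`
#' strata collapse the three-level code position exactly as validation
#' tables report it.
#'
#' @param sample sampled records (must carry `record_id`; `position` is
#'   needed for the position strata).
#' @param labels data frame with `record_id`, `truth`
#'   (`"acute_cvd"`/`"not_acute_cvd"`), and `category` for negatives.
#' @param stratum `"all"` (default), `"primary"` or `"secondary_or_others"`.
#' @inheritParams ppv_estimate
#' @return A [ppv_estimate()].
#' @export
estimate_ppv <- function(sample, labels, stratum = c("all", "primary", "secondary_or_others"),
                         conf_level = 0.95,
                         method = c("clopper-pearson", "wilson")) {
  stratum <- match.arg(stratum)
  keep <- switch(stratum,
                 all = rep(TRUE, nrow(sample)),
                 primary = sample$position == "primary",
                 secondary_or_others = sample$position != "primary")
  sub <- sample[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    phv_abort(sprintf("no sampled records in stratum '%s'", stratum),
              "phenoval_empty_arm")
  }
  lab <- join_labels(sub, labels)
  ppv_estimate(sum(lab$truth == "acute_cvd"), nrow(sub), stratum,
               conf_level = conf_level, method = match.arg(method))
}

#' Pool disjoint position-stratum PPV estimates
#'
#' Sums numerators and denominators over disjoint, exhaustive strata; the
#' pooled PPV equals the sample-size-weighted mean of the stratum PPVs in
#' exact rational arithmetic before any rounding.
#'
#' @param estimates list of [ppv_estimate()]s with pairwise-distinct
#'   stratum labels (none `"all"` when more than one is supplied).
#' @inheritParams ppv_estimate
#' @return A pooled [ppv_estimate()] with stratum `"all"`.
#' @export
pooled_ppv <- function(estimates, conf_level = 0.95,
                       method = c("clopper-pearson", "wilson")) {
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, inherits, logical(1), "ppv_estimate")))
  strata <- vapply(estimates, `[[`, "", "stratum")
  if (anyDuplicated(strata) || (length(estimates) > 1L && "all" %in% strata)) {
    phv_abort("strata to pool must be disjoint (distinct, non-'all' labels)",
              "phenoval_overlapping_strata")
  }
  if (length(estimates) == 1L) return(estimates[[1L]])
  k <- sum(vapply(estimates, `[[`, integer(1), "n_positive"))
  n <- sum(vapply(estimates, `[[`, integer(1), "n_sampled"))
  ppv_estimate(k, n, "all", conf_level = conf_level, method = match.arg(method))
}

#' Tally the non-disease categories of a reviewed sample
#'
#' Counts the false-positive mechanisms among records labelled
#' `not_acute_cvd`: history of stroke, stroke mimics (with a per-subtype
#' breakdown), and codes registered only for blood and/or imaging tests.
#' The tally total equals the number of non-positive labels.
#'
#' @param labels review labels for one arm's sample.
#' @return Object of class `nondisease_tally`: named integer vector over
#'   the three categories, with the mimic subtype table in
#'   `attr(, "mimic_subtypes")` and the total in `attr(, "total")`.
#' @export
tally_nondisease <- function(labels) {
  neg <- labels[labels$truth == "not_acute_cvd", , drop = FALSE]
  counts <- vapply(NONDISEASE_CATEGORIES,
                   function(cat) sum(neg$category == cat), integer(1))
  names(counts) <- NONDISEASE_CATEGORIES
  subtypes <- table(neg$mimic_subtype[neg$category == "stroke_mimic"])
  structure(counts, mimic_subtypes = subtypes, total = nrow(neg),
            class = "nondisease_tally")
}

#' @export
print.nondisease_tally <- function(x, ...) {
  cat(sprintf("<nondisease_tally> %d non-disease records\n", attr(x, "total")))
  for (nm in names(unclass(x))) cat(sprintf("  %s: %d\n", nm, x[[nm]]))
  st <- attr(x, "mimic_subtypes")
  if (length(st)) {
    cat("  mimic subtypes:\n")
    for (nm in names(st)) cat(sprintf("    %s: %d\n", nm, st[[nm]]))
  }
  invisible(x)
}

#' Run the review-and-estimation step over every arm
#'
#' For each arm: draw a seeded review sample, attach labels, and estimate
#' the PPV overall and within the position strata that the sample contains.
#'
#' @param assignments a [classify_arms()] result.
#' @param labels review labels covering the sampled records (e.g. from
#'   [auto_label()] or a completed reviewer worksheet); `NULL` to report
#'   arm counts only.
#' @param sample_size records to review per arm (default 100).
#' @param seed integer seed; each arm uses a distinct derived sub-seed.
#' @inheritParams ppv_estimate
#' @return Data frame with one row per arm x stratum: `arm`, `stratum`,
#'   `n_sampled`, `n_positive`, `ppv`, `ci_low`, `ci_high`, `percent`.
#'   The per-arm samples and tallies are kept in attributes `samples` and
#'   `tallies`.
#' @export
validate_arms <- function(assignments, labels, sample_size = 100L, seed,
                          conf_level = 0.95,
                          method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  seed <- check_seed(seed)
  arms <- arm_names(assignments)
  rows <- list()
  samples <- list()
  tallies <- list()
  for (i in seq_along(arms)) {
    arm <- arms[[i]]
    recs <- arm_records(assignments, arm)
    if (nrow(recs) == 0L) next
    smp <- withCallingHandlers(
      draw_review_sample(recs, sample_size, seed + i),
      phenoval_undersized_sample = function(w) invokeRestart("muffleWarning"))
    samples[[arm]] <- smp
    if (is.null(labels)) next
    lab <- join_labels(smp, labels)
    tallies[[arm]] <- tally_nondisease(lab)
    for (stratum in PPV_STRATA) {
      keep <- switch(stratum, all = TRUE,
                     primary = smp$position == "primary",
                     secondary_or_others = smp$position != "primary")
      if (!any(keep)) next
      est <- estimate_ppv(smp, labels, stratum, conf_level, method)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, stratum = stratum, n_sampled = est$n_sampled,
        n_positive = est$n_positive, ppv = est$ppv,
        ci_low = est$ci_low, ci_high = est$ci_high,
        percent = est$report_percent, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(arm = character(), stratum = character(), n_sampled = integer(),
               n_positive = integer(), ppv = numeric(), ci_low = numeric(),
               ci_high = numeric(), percent = integer(), stringsAsFactors = FALSE)
  attr(out, "samples") <- samples
  attr(out, "tallies") <- tallies
  attr(out, "seed") <- seed
  attr(out, "sample_size") <- sample_size
  out
}

#' Write the validation report
#'
#' Emits CSV and markdown versions of the arm x stratum PPV grid and, when
#' labels were available, the non-disease breakdown, with the seed and
#' sampling configuration echoed in a header. Without labels the report
#' contains the arm record counts only.
#'
#' @param assignments a [classify_arms()] result.
#' @param labels review labels or `NULL`.
#' @param out_dir output directory, created if needed.
#' @inheritParams validate_arms
#' @return Character vector of written file paths, invisibly.
#' @export
render_report <- function(assignments, labels = NULL, out_dir,
                          sample_size = 100L, seed,
                          conf_level = 0.95,
                          method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- arm_counts(assignments)
  counts_df <- data.frame(arm = names(counts), n_records = as.integer(counts),
                          stringsAsFactors = FALSE)
  paths <- file.path(out_dir, "arm_counts.csv")
  utils::write.csv(counts_df, paths, row.names = FALSE, quote = FALSE)
  header <- c(sprintf("seed: %d", check_seed(seed)),
              sprintf("sample_size: %d", sample_size),
              sprintf("ci_method: %s (%.0f%%)", method, 100 * conf_level))
  md <- c("# Validation report", "", header, "", "## Arm sizes", "",
          md_table(counts_df))
  if (!is.null(labels)) {
    res <- validate_arms(assignments, labels, sample_size, seed, conf_level, method)
    ppv_path <- file.path(out_dir, "ppv_by_arm.csv")
    utils::write.csv(res, ppv_path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, ppv_path)
    md <- c(md, "", "## PPV by arm and code position", "", md_table(res))
    tallies <- attr(res, "tallies")
    if (length(tallies)) {
      bd <- do.call(rbind, lapply(names(tallies), function(arm) {
        t <- tallies[[arm]]
        data.frame(arm = arm, category = names(unclass(t)),
                   n = as.integer(unclass(t)), stringsAsFactors = FALSE)
      }))
      bd_path <- file.path(out_dir, "nondisease_breakdown.csv")
      utils::write.csv(bd, bd_path, row.names = FALSE, quote = FALSE)
      paths <- c(paths, bd_path)
      md <- c(md, "", "## Non-disease breakdown", "", md_table(bd))
    }
  }
  md_path <- file.path(out_dir, "report.md")
  writeLines(md, md_path)
  invisible(c(paths, md_path))
}
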