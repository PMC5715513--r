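# ICD-10 code normalization and set membership.
#
# A code set combines exact codes (e.g. G458), 3-character category prefixes
# (I63 matches I63, I630, I639, ...), and inclusive category ranges written
# in ICD-10 block notation (I10-I15). Ranges are category-level: a code
# belongs to a range when its first three characters fall inside it.

#' Normalize an ICD-10 code string
#'
#' Uppercases, strips surrounding whitespace and removes the dot, so that
#' `"i63.9 "` becomes `"I639"`. Vectorized.
#'
#' @param raw character vector of raw codes.
#' @return Character vector of normalized codes.
#' @export
normalize_code <- function(raw) {
  if (length(raw) == 0L) return(character())
  x <- gsub(".", "", trimws(toupper(raw)), fixed = TRUE)
  empty <- !nzchar(x)
  if (any(empty)) {
    phv_abort(sprintf("empty code in position(s) %s",
                      paste(utils::head(which(empty), 5L), collapse = ", ")),
              "phenoval_bad_code")
  }
  bad <- !grepl("^[A-Z][0-9]{2}[A-Z0-9]*$", x)
  if (any(bad)) {
    phv_abort(sprintf("code(s) not matching letter+digits ICD-10 pattern: %s",
                      paste(utils::head(x[bad], 5L), collapse = ", ")),
              "phenoval_bad_code")
  }
  x
}

check_category <- function(x, what) {
  bad <- !grepl("^[A-Z][0-9]{2}$", x)
  if (any(bad)) {
    phv_abort(sprintf("%s must be 3-character ICD-10 categories (letter + 2 digits): %s",
                      what, paste(x[bad], collapse = ", ")),
              "phenoval_bad_code")
  }
  x
}

#' Define a named ICD-10 code set
#'
#' @param name label for the set.
#' @param exact_codes exact normalized codes (dot allowed; normalized here).
#' @param category_prefixes 3-character categories matching any code that
#'   starts with them.
#' @param category_ranges list of inclusive category ranges, each a
#'   2-element character vector such as `c("I10", "I15")`.
#' @return An object of class `code_set`.
#' @export
code_set <- function(name, exact_codes = character(),
                     category_prefixes = character(),
                     category_ranges = list()) {
  exact <- if (length(exact_codes)) normalize_code(exact_codes) else character()
  prefixes <- check_category(toupper(category_prefixes), "category_prefixes")
  ranges <- lapply(category_ranges, function(r) {
    r <- check_category(toupper(r), "category_ranges")
    if (length(r) != 2L) {
      phv_abort("each category range must have exactly two endpoints",
                "phenoval_bad_code")
    }
    if (substr(r[1], 1, 1) != substr(r[2], 1, 1) || r[1] > r[2]) {
      phv_abort(sprintf("invalid category range %s-%s", r[1], r[2]),
                "phenoval_bad_code")
    }
    r
  })
  structure(list(name = name, exact_codes = exact,
                 category_prefixes = prefixes, category_ranges = ranges),
            class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  rng <- vapply(x$category_ranges, function(r) paste(r, collapse = "-"), "")
  cat(sprintf("<code_set> %s\n", x$name))
  if (length(x$exact_codes)) cat("  exact:    ", paste(x$exact_codes, collapse = ", "), "\n")
  if (length(x$category_prefixes)) cat("  prefixes: ", paste(x$category_prefixes, collapse = ", "), "\n")
  if (length(rng)) cat("  ranges:   ", paste(rng, collapse = ", "), "\n")
  invisible(x)
}

#' Test membership of normalized codes in a code set
#'
#' A code matches when it equals an exact member, when its 3-character
#' category is a listed prefix, or when that category lies inside any
#' inclusive range. Vectorized over `code`.
#'
#' @param code character vector of normalized codes.
#' @param set a [code_set()].
#' @return Logical vector.
#' @export
match_code <- function(code, set) {
  stopifnot(inherits(set, "code_set"))
  if (length(code) == 0L) return(logical())
  category <- substr(code, 1L, 3L)
  hit <- code %in% set$exact_codes | category %in% set$category_prefixes
  for (r in set$category_ranges) {
    # fixed-width categories make lexicographic comparison equal numeric order
    hit <- hit | (category >= r[1] & category <= r[2])
  }
  hit
}

#' Extract the diagnosis records matching a code set
#'
#' Order-preserving subset of the diagnosis table; partitionable downstream
#' by the definite/suspected certainty flag.
#'
#' @param diagnoses diagnosis table (as in [load_bundle()]).
#' @param set a [code_set()].
#' @return Subset of `diagnoses`.
#' @export
extract_codes <- function(diagnoses, set) {
  diagnoses[match_code(diagnoses$code, set), , drop = FALSE]
}

#' Cohort prevalence of a code set
#'
#' A patient carrying at least one matching code counts once, however many
#' matching registrations they have. Only carriers present in the supplied
#' (cleaned) patient table are counted.
#'
#' @param patients cleaned patient table.
#' @param diagnoses diagnosis table.
#' @param set a [code_set()].
#' @return List with `n_carriers`, `n_patients`, `proportion` and `percent`
#'   (one decimal, as reported).
#' @export
prevalence <- function(patients, diagnoses, set) {
  if (nrow(patients) == 0L) {
    phv_abort("prevalence is undefined on an empty patient table",
              "phenoval_empty_cohort")
  }
  hits <- extract_codes(diagnoses, set)
  carriers <- intersect(unique(hits$patient_id), patients$patient_id)
  n <- nrow(patients)
  k <- length(carriers)
  list(n_carriers = k, n_patients = n, proportion = k / n,
       percent = round(100 * k / n, 1L))
}

#' Code sets shipped with the package
#'
#' Reads the packaged YAML declaration of the stroke code set
#' (I60/I61/I63 categories plus exact G458 and G459 — deliberately not the
#' whole G45 category) and the covariate sets: hypertension (I10-I15),
#' diabetes (E10-E14), dyslipidemia (E78), atrial fibrillation (I48) and
#' brain metastases (exact C793).
#'
#' @param path YAML file; defaults to the packaged `code_sets.yaml`.
#' @return Named list of [code_set()] objects.
#' @export
default_code_sets <- function(path = system.file("extdata", "code_sets.yaml",
                                                 package = "phenoval")) {
  spec <- yaml::read_yaml(path)
  out <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    code_set(nm,
             exact_codes = unlist(s$exact_codes) %||% character(),
             category_prefixes = unlist(s$category_prefixes) %||% character(),
             category_ranges = s$category_ranges %||% list())
  })
  names(out) <- names(spec)
  out
}

#' The stroke code set used throughout the validation pipeline
#' @return A [code_set()].
#' @export
stroke_code_set <- function() default_code_sets()$stroke
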