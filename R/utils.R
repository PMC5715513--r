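# Internal helpers shared across modules.

# Classed condition so callers can distinguish failure modes programmatically.
phv_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "phenoval_error")))
}

phv_warn <- function(message, class, ...) {
  warning(warningCondition(message, ..., class = c(class, "phenoval_warning")))
}

# Nearest-integer rounding with ties away from zero (round() rounds half to
# even, which does not reproduce printed report percentages such as 50.5 -> 51).
round_half_away <- function(x) {
  as.integer(sign(x) * trunc(abs(x) + 0.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

check_seed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed) || !is.numeric(seed)) {
    phv_abort("`seed` must be a single integer", "phenoval_bad_config")
  }
  if (abs(seed) > 2^31 - 1000) {
    phv_abort("`seed` must lie within 32-bit integer range", "phenoval_bad_config")
  }
  as.integer(seed)
}

# The registry's enrolment window; all synthetic dates fall inside it.
study_window <- function() {
  c(as.Date("2007-01-01"), as.Date("2015-12-31"))
}

# Plain-text pipe table used by render_report().
md_table <- function(df) {
  cells <- as.data.frame(lapply(df, function(x) {
    if (is.numeric(x) && !is.integer(x)) formatC(x, format = "fg", digits = 4) else as.character(x)
  }), stringsAsFactors = FALSE)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}
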