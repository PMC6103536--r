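# Typed conditions -----------------------------------------------------------

prism_abort <- function(message, class, ...) {
  abort(message, class = c(class, "prism_error"), ...)
}

stop_empty_feature_set <- function(name) {
  prism_abort(
    sprintf("Feature set '%s' overlaps no peak in the universe.", name),
    class = "prism_error_empty_feature_set"
  )
}

stop_insufficient_cells <- function(n_usable) {
  prism_abort(
    sprintf("Only %d cell(s) have accessible peaks in this subset; at least 3 are required.", n_usable),
    class = "prism_error_insufficient_cells"
  )
}

stop_zero_vector <- function() {
  prism_abort(
    "Angular cosine distance is undefined for an all-zero accessibility vector.",
    class = "prism_error_zero_vector"
  )
}

stop_unmatchable <- function(peak_ids, gc) {
  prism_abort(
    c(
      "No admissible background assignment exists at the configured tolerances.",
      "x" = sprintf(
        "Hardest peaks to match: %s (gc %s).",
        paste(head(peak_ids, 5), collapse = ", "),
        paste(signif(head(gc, 5), 3), collapse = ", ")
      ),
      "i" = "Consider widening `gc_tolerance` or `accessibility_tolerance`."
    ),
    class = "prism_error_unmatchable_peak",
    peak_ids = peak_ids
  )
}

stop_degenerate_background <- function() {
  prism_abort(
    "All background peak sets have zero variability; the bias-corrected ratio is undefined.",
    class = "prism_error_degenerate_background"
  )
}

# Seed streams ----------------------------------------------------------------

# Deterministic 31-bit integer streams derived from one master seed, so that
# iteration i always sees the same sub-seed no matter how many iterations run.
derive_seed <- function(master, ...) {
  labels <- c(...)
  h <- as.double(master %% 2147483647L)
  for (x in labels) {
    for (ch in utf8ToInt(as.character(x))) {
      h <- (h * 31 + ch) %% 2147483647
    }
    h <- (h * 48271) %% 2147483647
  }
  as.integer(h)
}

with_stream <- function(master, ..., code) {
  withr::with_seed(derive_seed(master, ...), code)
}

# Coerce any Matrix flavour (pattern, logical, triplet) to numeric dgCMatrix.
as_dgc <- function(m) {
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}
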