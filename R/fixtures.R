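#' Specification for a synthetic peak-by-cell universe
#'
#' Describes a download-free stand-in for a real open-chromatin universe:
#' per-peak accessibility probabilities, per-peak GC contents, and optional
#' feature blocks carrying injected heterogeneity. Entries of the binary
#' matrix are independent coin flips with the peak's probability.
#'
#' Accessibility profiles:
#' * `"calibration"` (default): probabilities tightly grouped around 0.275
#'   (truncated normal, sd 0.008, clipped to `[0.05, 0.5]`). With a
#'   peak-for-peak background-matching window of ±0.01 on mean accessibility,
#'   the binomial measurement noise of a few hundred cells is the limiting
#'   factor; this profile keeps an ample matched-candidate pool so the full
#'   two-stage normalization runs at desk scale.
#' * `"broad"`: uniform on `[0.05, 0.5]`, emulating the wide dynamic range of
#'   per-peak accessibility in real peak universes.
#' * `"bimodal"`: half the peaks rarely accessible (0.1), half commonly
#'   (0.5), a two-block universe giving the titration benchmark well-separated
#'   accessibility patterns.
#'
#' @param n_cells,n_peaks Universe dimensions (defaults 200 x 2000, a desk
#'   scale stand-in for the ~50,000-peak universes of real data).
#' @param acc_profile One of `"calibration"`, `"broad"`, `"bimodal"`; ignored
#'   when `acc_probs` is given.
#' @param acc_probs Optional explicit per-peak probability vector in `(0, 1)`.
#' @param gc Optional explicit per-peak GC vector; by default Beta(3, 3)
#'   scaled to `[0.2, 0.8]` (bell-shaped with thin tails, so peak-for-peak GC
#'   windows at the extremes remain coverable at desk scale).
#' @param blocks Optional named list of integer peak-index vectors defining
#'   feature blocks (see [inject_block_heterogeneity()]).
#' @param seed Master seed; all randomness derives from it.
#' @return A `prism_fixture_spec` list.
#' @export
fixture_spec <- function(n_cells = 200L, n_peaks = 2000L,
                         acc_profile = c("calibration", "broad", "bimodal"),
                         acc_probs = NULL, gc = NULL, blocks = list(),
                         seed = 1L) {
  acc_profile <- match.arg(acc_profile)
  if (!is.null(acc_probs) && length(acc_probs) != n_peaks) {
    prism_abort("`acc_probs` must have one entry per peak.", class = "prism_error_bad_value")
  }
  if (!is.null(gc) && length(gc) != n_peaks) {
    prism_abort("`gc` must have one entry per peak.", class = "prism_error_bad_value")
  }
  structure(
    list(n_cells = as.integer(n_cells), n_peaks = as.integer(n_peaks),
         acc_profile = acc_profile, acc_probs = acc_probs, gc = gc,
         blocks = blocks, seed = as.integer(seed)),
    class = "prism_fixture_spec"
  )
}

draw_profile <- function(profile, n) {
  switch(profile,
    calibration = pmin(0.5, pmax(0.05, rnorm(n, 0.275, 0.008))),
    broad = runif(n, 0.05, 0.5),
    bimodal = sample(c(0.1, 0.5), n, replace = TRUE)
  )
}

#' Generate a null synthetic universe
#'
#' Entries are independent Bernoulli draws with each peak's probability; no
#' cell-to-cell structure exists beyond sampling noise, so any feature subset
#' is exchangeable with background. Peaks get fabricated non-overlapping
#' coordinates on one pseudo-chromosome, the given GC values, and their
#' empirical mean accessibility.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `binary` (sparse 0/1 cells-by-peaks matrix), `peaks`
#'   (annotated [peak_table()]), `probs` (the generating probabilities).
#' @export
generate_null_universe <- function(spec = fixture_spec()) {
  out <- withr::with_seed(spec$seed, {
    probs <- spec$acc_probs %||% draw_profile(spec$acc_profile, spec$n_peaks)
    gc <- spec$gc %||% (0.2 + 0.6 * stats::rbeta(spec$n_peaks, 3, 3))
    X <- matrix(
      rbinom(spec$n_cells * spec$n_peaks, 1L, rep(probs, each = spec$n_cells)),
      nrow = spec$n_cells, ncol = spec$n_peaks
    )
    list(probs = probs, gc = gc, X = X)
  })
  cell_ids <- sprintf("cell_%04d", seq_len(spec$n_cells))
  starts <- (seq_len(spec$n_peaks) - 1L) * 1000L
  peaks <- peak_table(
    chrom = "chrS", start = starts, end = starts + 500L,
    peak_id = sprintf("peak_%05d", seq_len(spec$n_peaks)),
    gc = out$gc
  )
  binary <- as_dgc(Matrix::Matrix(out$X, sparse = TRUE))
  dimnames(binary) <- list(cell_ids, peaks$peak_id)
  peaks$mean_accessibility <- as.numeric(Matrix::colMeans(binary))
  list(binary = binary, peaks = peaks, probs = out$probs)
}

#' Inject two-population heterogeneity into a peak block
#'
#' Splits cells into two halves and the block's peaks into two interleaved
#' sub-blocks (interleaved after sorting by probability, so the sub-blocks
#' have equal expected totals). With intensity `h`, each cell independently
#' becomes a "specialist" with probability `h`: its accessibility over the
#' whole block is redrawn with doubled rates on its own half's sub-block and
#' zero on the other, keeping its expected total accessibility in the block
#' unchanged. At `h = 1` the two halves have disjoint accessible sub-blocks
#' and between-half angular distances at the block approach 1; at `h = 0` the
#' matrix is unchanged.
#'
#' This emulates heterogeneity in which cells hold comparable total
#' accessibility but are accessible at different regulatory elements.
#'
#' @param universe A list from [generate_null_universe()] (needs `binary`,
#'   `probs`).
#' @param block Integer peak indices (or a [feature_set()]).
#' @param h Heterogeneity intensity in `[0, 1]`.
#' @param seed Seed for the redraw.
#' @return The universe with `binary` modified and `peaks$mean_accessibility`
#'   refreshed.
#' @export
inject_block_heterogeneity <- function(universe, block, h, seed = 1L) {
  if (h < 0 || h > 1) {
    prism_abort("`h` must lie in [0, 1].", class = "prism_error_bad_value")
  }
  idx <- if (inherits(block, "prism_feature_set")) block$peak_indices else as.integer(block)
  if (max(2 * universe$probs[idx]) > 1) {
    prism_abort("Block probabilities must not exceed 0.5 (doubled rates must stay <= 1).",
                class = "prism_error_bad_value")
  }
  if (h == 0) return(universe)
  X <- as.matrix(universe$binary)
  n <- nrow(X)
  half <- c(rep(1L, ceiling(n / 2)), rep(2L, floor(n / 2)))
  ordb <- idx[order(universe$probs[idx])]
  sub <- list(ordb[seq(1, length(ordb), 2)], ordb[seq(2, length(ordb), 2)])
  withr::with_seed(seed, {
    specialist <- rbinom(n, 1L, h) == 1L
    for (cell in which(specialist)) {
      X[cell, idx] <- 0L
      own <- sub[[half[cell]]]
      X[cell, own] <- rbinom(length(own), 1L, 2 * universe$probs[own])
    }
  })
  binary <- as_dgc(Matrix::Matrix(X, sparse = TRUE))
  dimnames(binary) <- dimnames(universe$binary)
  universe$binary <- binary
  universe$peaks$mean_accessibility <- as.numeric(Matrix::colMeans(binary))
  universe$half <- half
  universe
}

#' Write a synthetic universe as a standard matrix bundle
#'
#' Emits the Matrix Market matrix, peak BED, barcode list and annotated peak
#' table, so fixtures are indistinguishable from real inputs to the rest of
#' the package.
#'
#' @param universe A list from [generate_null_universe()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture_bundle <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, "matrix.mtx"),
    peaks = file.path(dir, "peaks.bed"),
    barcodes = file.path(dir, "barcodes.tsv"),
    annotated = file.path(dir, "peaks_annotated.tsv")
  )
  write_peak_matrix(universe$binary, universe$peaks,
                    paths["matrix"], paths["peaks"], paths["barcodes"])
  write_peak_table(universe$peaks, paths["annotated"])
  invisible(paths)
}
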