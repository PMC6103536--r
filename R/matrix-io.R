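#' Read a peak-by-cell matrix bundle
#'
#' Loads a Matrix Market triplet file together with its sidecar peak BED and
#' barcode list, and returns counts oriented as cells-by-peaks regardless of
#' the on-disk orientation. Orientation is resolved by matching the matrix
#' dimensions to the number of peaks and barcodes; a square matrix is
#' ambiguous and requires an explicit `orientation`.
#'
#' @param matrix_path Matrix Market (`.mtx`, optionally gzipped) triplet file.
#' @param peaks_path BED3+ file of peak intervals (optionally gzipped).
#' @param barcodes_path Text file with one cell barcode per line (optionally
#'   gzipped).
#' @param orientation `"auto"` (default), `"cells_by_peaks"` or
#'   `"peaks_by_cells"`, describing the on-disk layout.
#'
#' @return A list with elements `counts` (a sparse [Matrix::dgCMatrix-class],
#'   cells as rows, peaks as columns, dimnames set from barcodes and peak ids)
#'   and `peaks` (a [peak_table()]; column order of `counts` follows it).
#' @export
read_peak_matrix <- function(matrix_path, peaks_path, barcodes_path,
                             orientation = c("auto", "cells_by_peaks", "peaks_by_cells")) {
  orientation <- match.arg(orientation)
  m <- read_mm(matrix_path)
  bed <- read_bed(peaks_path)
  if (anyDuplicated(bed[c("chrom", "start", "end")])) {
    prism_abort("Duplicated peak coordinates in the peak BED file.",
                class = "prism_error_duplicate_peaks")
  }
  barcodes <- readr::read_lines(barcodes_path, progress = FALSE)
  barcodes <- barcodes[nzchar(barcodes)]
  n_peaks <- nrow(bed)
  n_cells <- length(barcodes)

  if (orientation == "auto") {
    if (n_peaks == n_cells && nrow(m) == ncol(m)) {
      prism_abort(
        "Square matrix with equal peak and barcode counts: pass `orientation` explicitly.",
        class = "prism_error_ambiguous_orientation"
      )
    }
    orientation <- if (nrow(m) == n_cells && ncol(m) == n_peaks) {
      "cells_by_peaks"
    } else if (nrow(m) == n_peaks && ncol(m) == n_cells) {
      "peaks_by_cells"
    } else {
      prism_abort(
        sprintf(
          "Matrix is %d x %d but the sidecars declare %d peak(s) and %d barcode(s).",
          nrow(m), ncol(m), n_peaks, n_cells
        ),
        class = "prism_error_dimension_mismatch"
      )
    }
  } else {
    expected <- if (orientation == "cells_by_peaks") c(n_cells, n_peaks) else c(n_peaks, n_cells)
    if (!identical(dim(m), as.integer(expected))) {
      prism_abort(
        sprintf(
          "Matrix is %d x %d but the sidecars declare %d peak(s) and %d barcode(s).",
          nrow(m), ncol(m), n_peaks, n_cells
        ),
        class = "prism_error_dimension_mismatch"
      )
    }
  }
  if (orientation == "peaks_by_cells") m <- Matrix::t(m)

  peaks <- peak_table(bed$chrom, bed$start, bed$end,
                      peak_id = if ("name" %in% names(bed)) bed$name else NULL)
  # columns follow the (sorted) peak table; recover the BED-order -> sorted map
  bed_ids <- if ("name" %in% names(bed)) bed$name else sprintf("%s:%d-%d", bed$chrom, bed$start, bed$end)
  m <- m[, match(peaks$peak_id, bed_ids), drop = FALSE]
  dimnames(m) <- list(barcodes, peaks$peak_id)
  list(counts = as_dgc(m), peaks = peaks)
}

read_mm <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    Matrix::readMM(con)
  } else {
    Matrix::readMM(path)
  }
}

#' Write a peak-by-cell matrix bundle
#'
#' Inverse of [read_peak_matrix()]: writes the matrix in Matrix Market triplet
#' format (cells as rows), the peak table as BED4 and the barcodes one per
#' line.
#'
#' @param counts Cells-by-peaks matrix with dimnames.
#' @param peaks The matching [peak_table()].
#' @param matrix_path,peaks_path,barcodes_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_peak_matrix <- function(counts, peaks, matrix_path, peaks_path, barcodes_path) {
  Matrix::writeMM(methods::as(as_dgc(counts), "TsparseMatrix"), matrix_path)
  writeLines(sprintf("%s\t%d\t%d\t%s", peaks$chrom, peaks$start, peaks$end, peaks$peak_id),
             peaks_path)
  writeLines(rownames(counts), barcodes_path)
  invisible(matrix_path)
}

#' Binarize an accessibility count matrix
#'
#' Scores a region accessible (1) in a cell when its count reaches
#' `threshold`, inaccessible (0) otherwise. The default threshold of 1 treats
#' any read as evidence of accessibility.
#'
#' @param counts Non-negative cells-by-peaks count matrix (dense or sparse).
#' @param threshold Positive integer count threshold.
#' @return A sparse 0/1 cells-by-peaks matrix with the same dimnames.
#' @export
binarize <- function(counts, threshold = 1L) {
  if (threshold < 1) {
    prism_abort("`threshold` must be a positive integer.", class = "prism_error_bad_value")
  }
  if (min_value(counts) < 0) {
    prism_abort("Counts must be non-negative.", class = "prism_error_bad_value")
  }
  out <- Matrix::drop0(as_dgc(counts >= threshold))
  dimnames(out) <- dimnames(counts)
  out
}

min_value <- function(m) {
  if (methods::is(m, "nsparseMatrix")) return(0)  # pattern matrix: entries are 0/1
  if (methods::is(m, "sparseMatrix")) {
    x <- as_dgc(m)@x
    if (length(x)) min(x, 0) else 0
  } else {
    min(m)
  }
}

#' Per-cell total accessibility
#'
#' The number of accessible regions in each cell (row sums of the binary
#' matrix).
#'
#' @param binary A 0/1 cells-by-peaks matrix.
#' @return Named integer vector, one entry per cell.
#' @export
total_accessibility <- function(binary) {
  setNames(as.integer(round(Matrix::rowSums(binary))), rownames(binary))
}

#' Per-peak mean accessibility
#'
#' Fraction of cells in which each peak is accessible (column means of the
#' binary matrix).
#'
#' @param binary A 0/1 cells-by-peaks matrix with at least one cell.
#' @return Named numeric vector in `[0, 1]`, one entry per peak.
#' @export
mean_accessibility <- function(binary) {
  if (nrow(binary) == 0L) {
    prism_abort("The matrix has no cells.", class = "prism_error_bad_value")
  }
  setNames(as.numeric(Matrix::colMeans(binary)), colnames(binary))
}

#' Define a feature peak set by index
#'
#' @param peak_indices Unique, in-range indices into the peak universe.
#' @param name Label for the feature (e.g. a transcription factor).
#' @param n_universe Number of peaks in the universe, for validation.
#' @return A `prism_feature_set` object.
#' @export
feature_set <- function(peak_indices, name = "feature", n_universe = NULL) {
  idx <- as.integer(peak_indices)
  if (length(idx) == 0L) stop_empty_feature_set(name)
  if (anyDuplicated(idx)) {
    prism_abort("Feature peak indices must be unique.", class = "prism_error_bad_value")
  }
  if (any(idx < 1L) || (!is.null(n_universe) && any(idx > n_universe))) {
    prism_abort("Feature peak indices out of range.", class = "prism_error_bad_value")
  }
  structure(list(name = name, peak_indices = idx), class = "prism_feature_set")
}

#' @export
print.prism_feature_set <- function(x, ...) {
  cat(sprintf("<prism_feature_set> '%s': %d peaks\n", x$name, length(x$peak_indices)))
  invisible(x)
}

#' @export
length.prism_feature_set <- function(x) length(x$peak_indices)

#' Map feature intervals onto the peak universe
#'
#' Returns the peaks overlapping any feature interval by at least
#' `min_overlap_bp` bases. Both interval sets must share the assembly and the
#' BED 0-based half-open convention; touching intervals do not overlap, and
#' strand is ignored.
#'
#' @param peaks A [peak_table()] (the peak universe).
#' @param feature_intervals A tibble/data.frame with `chrom`, `start`, `end`
#'   (e.g. from [read_bed()]).
#' @param min_overlap_bp Minimum overlap in base pairs (default 1).
#' @param name Feature label.
#' @return A [feature_set()] of peak indices into `peaks`.
#' @export
map_feature_to_peaks <- function(peaks, feature_intervals, min_overlap_bp = 1L,
                                 name = "feature") {
  q <- peaks_as_granges(peaks)
  s <- GenomicRanges::GRanges(
    seqnames = feature_intervals$chrom,
    ranges = IRanges::IRanges(start = feature_intervals$start + 1L,
                              end = feature_intervals$end)
  )
  # disjoint chromosome sets are an expected outcome (no overlap), not a problem
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, s, minoverlap = min_overlap_bp,
                                ignore.strand = TRUE)
  )
  idx <- sort(unique(S4Vectors_queryHits(hits)))
  if (length(idx) == 0L) stop_empty_feature_set(name)
  feature_set(idx, name = name, n_universe = nrow(peaks))
}

# thin indirection so S4Vectors need not be attached
S4Vectors_queryHits <- function(hits) methods::slot(hits, "from")
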