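#' Build a validated peak table
#'
#' A peak table is a tibble of open-chromatin intervals — the columns of the
#' peak-by-cell matrix — in BED convention (0-based start, exclusive end), with
#' optional per-peak GC fraction and mean accessibility (fraction of cells in
#' which the peak is accessible). Rows are sorted by `(chrom, start)`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer interval bounds, 0-based half-open.
#' @param peak_id Unique peak identifiers; defaults to `chrom:start-end`.
#' @param gc Per-peak GC fraction in `[0, 1]`, or `NA` where unknown.
#' @param mean_accessibility Per-peak fraction of cells accessible, or `NA`.
#'
#' @return A tibble with class `prism_peaks`, columns `chrom`, `start`, `end`,
#'   `peak_id`, `gc`, `mean_accessibility`.
#' @export
peak_table <- function(chrom, start, end, peak_id = NULL,
                       gc = NA_real_, mean_accessibility = NA_real_) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start >= end)) {
    prism_abort("All peaks must satisfy start < end.", class = "prism_error_bad_interval")
  }
  if (is.null(peak_id)) peak_id <- sprintf("%s:%d-%d", chrom, start, end)
  if (anyDuplicated(peak_id)) {
    prism_abort("Peak identifiers must be unique.", class = "prism_error_duplicate_peaks")
  }
  check_unit_interval(gc, "gc")
  check_unit_interval(mean_accessibility, "mean_accessibility")
  out <- tibble(
    chrom = as.character(chrom), start = start, end = end,
    peak_id = as.character(peak_id),
    gc = vec_recycle_num(gc, length(chrom)),
    mean_accessibility = vec_recycle_num(mean_accessibility, length(chrom))
  )
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  class(out) <- c("prism_peaks", class(out))
  out
}

check_unit_interval <- function(x, what) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    prism_abort(sprintf("`%s` values must lie in [0, 1].", what),
                class = "prism_error_bad_value")
  }
}

vec_recycle_num <- function(x, n) {
  x <- as.numeric(x)
  if (length(x) == 1L) rep(x, n) else x
}

#' Read a BED3+ interval file
#'
#' Columns beyond the first six are ignored; a fourth column, when present, is
#' used as the interval name. Gzip input is accepted.
#'
#' @param path Path to a BED file (optionally gzipped).
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 3L) {
    prism_abort(sprintf("'%s' is not a BED3+ file (found %d columns).", path, ncol(raw)),
                class = "prism_error_bad_bed")
  }
  out <- tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]])
  )
  if (ncol(raw) >= 4L) out$name <- raw[[4]]
  out
}

#' Write an annotated peak table as BED6+ with gc and accessibility columns
#'
#' Emits a tab-separated file: `chrom start end peak_id score strand gc
#' mean_accessibility`, with a single `#`-prefixed header naming the columns.
#' Strand is always `.` (accessibility is strandless); score is `0`.
#'
#' @param peaks A [peak_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  lines <- c(
    "#chrom\tstart\tend\tpeak_id\tscore\tstrand\tgc\tmean_accessibility",
    sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t%s",
            peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
            format_na(peaks$gc), format_na(peaks$mean_accessibility))
  )
  writeLines(lines, path)
  invisible(path)
}

format_na <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))

#' Read a peak table written by [write_peak_table()]
#'
#' @param path Path to the annotated BED6+ file.
#' @return A `prism_peaks` tibble.
#' @export
read_peak_table <- function(path) {
  raw <- read_bed(path)
  full <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  peak_table(
    chrom = raw$chrom, start = raw$start, end = raw$end, peak_id = raw$name,
    gc = suppressWarnings(as.numeric(full[[7]])),
    mean_accessibility = suppressWarnings(as.numeric(full[[8]]))
  )
}

peaks_as_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}
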