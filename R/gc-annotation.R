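#' Annotate peaks with GC fraction from a genome FASTA
#'
#' GC is computed over the peak interval as given:
#' `(#G + #C) / (#A + #C + #G + #T)`, case-insensitive. `N` and other
#' ambiguity codes are excluded from the denominator, so the value is the GC
#' fraction of the determined bases. Peaks whose sequence is entirely
#' undetermined get `NA` and are reported via the `all_n` attribute; they are
#' excluded from background-matching candidacy rather than imputed.
#'
#' @param peaks A [peak_table()].
#' @param genome Path to a FASTA file; a `.fai` index is created if absent.
#' @return `peaks` with the `gc` column filled; attribute `all_n` lists peak
#'   ids whose sequence had no determined base.
#' @export
compute_gc <- function(peaks, genome) {
  fa <- Rsamtools::FaFile(genome)
  if (!file.exists(paste0(genome, ".fai"))) Rsamtools::indexFa(genome)
  info <- Rsamtools::seqinfo(fa)
  missing_chrom <- setdiff(unique(peaks$chrom), GenomeInfoDb_seqnames(info))
  if (length(missing_chrom)) {
    offending <- peaks$peak_id[peaks$chrom %in% missing_chrom]
    prism_abort(
      c(
        sprintf("Chromosome(s) %s absent from '%s'.",
                paste(missing_chrom, collapse = ", "), genome),
        "x" = sprintf("Offending peaks: %s%s",
                      paste(head(offending, 10), collapse = ", "),
                      if (length(offending) > 10) ", ..." else "")
      ),
      class = "prism_error_missing_chrom"
    )
  }
  lens <- setNames(GenomeInfoDb_seqlengths(info), GenomeInfoDb_seqnames(info))
  too_long <- peaks$end > lens[peaks$chrom]
  if (any(too_long)) {
    prism_abort(
      sprintf("Peak(s) %s extend beyond their chromosome.",
              paste(head(peaks$peak_id[too_long], 10), collapse = ", ")),
      class = "prism_error_bad_interval"
    )
  }
  seqs <- Rsamtools::scanFa(fa, peaks_as_granges(peaks))
  gc_counts <- Biostrings::letterFrequency(seqs, letters = c("G", "C"))
  acgt <- rowSums(Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T")))
  gc <- ifelse(acgt > 0, rowSums(gc_counts) / acgt, NA_real_)
  peaks$gc <- as.numeric(gc)
  attr(peaks, "all_n") <- peaks$peak_id[acgt == 0]
  peaks
}

GenomeInfoDb_seqnames <- function(info) methods::slot(info, "seqnames")
GenomeInfoDb_seqlengths <- function(info) methods::slot(info, "seqlengths")

#' Annotate peaks with GC content and mean accessibility
#'
#' Convenience wrapper filling both annotation columns used by background
#' matching.
#'
#' @param peaks A [peak_table()] aligned to the columns of `binary`.
#' @param binary A 0/1 cells-by-peaks matrix.
#' @param genome Optional FASTA path; when `NULL`, `gc` is left as is.
#' @return The annotated peak table.
#' @export
annotate_peaks <- function(peaks, binary, genome = NULL) {
  if (!is.null(genome)) peaks <- compute_gc(peaks, genome)
  acc <- mean_accessibility(binary)
  if (!is.null(colnames(binary))) {
    peaks$mean_accessibility <- as.numeric(acc[peaks$peak_id])
  } else {
    stopifnot(length(acc) == nrow(peaks))
    peaks$mean_accessibility <- as.numeric(acc)
  }
  peaks
}
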