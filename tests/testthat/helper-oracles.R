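# Shared fixture builders and independent oracles used across tests.

# Write a Matrix Market triplet file by hand (independent of Matrix::writeMM).
write_mtx <- function(path, nrow, ncol, entries) {
  # entries: data.frame(i, j, x)
  lines <- c(
    "%%MatrixMarket matrix coordinate integer general",
    sprintf("%d %d %d", nrow, ncol, nrow(entries)),
    if (nrow(entries)) sprintf("%d %d %d", entries$i, entries$j, entries$x)
  )
  writeLines(lines, path)
  path
}

write_bed_file <- function(path, chrom, start, end, name = NULL) {
  df <- if (is.null(name)) {
    sprintf("%s\t%d\t%d", chrom, start, end)
  } else {
    sprintf("%s\t%d\t%d\t%s", chrom, start, end, name)
  }
  writeLines(df, path)
  path
}

write_barcodes <- function(path, ids) {
  writeLines(ids, path)
  path
}

write_fasta <- function(path, seqs) {
  lines <- unlist(lapply(names(seqs), function(nm) c(paste0(">", nm), seqs[[nm]])))
  writeLines(lines, path)
  path
}

# All-pairs interval overlap scan (0-based half-open), the brute-force oracle
# for map_feature_to_peaks().
brute_force_overlap <- function(peaks, features, min_overlap_bp = 1L) {
  hit <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(features))) {
      if (peaks$chrom[i] != features$chrom[j]) next
      ov <- min(peaks$end[i], features$end[j]) - max(peaks$start[i], features$start[j])
      if (ov >= min_overlap_bp) hit[i] <- TRUE
    }
  }
  which(hit)
}

# Reference (non-compiled) route to the variability statistic, via the public
# distance and embedding functions.
dispersion_reference <- function(binary, feature) {
  emb <- pcoa_embed(pairwise_distances(binary, feature))
  if (ncol(emb$coords) == 0) return(0)
  mean(sqrt(rowSums(emb$coords^2)))
}

# Random feature draws conditioned on background-matchability at the given
# tolerances (unmatchable draws are rare and redrawn deterministically).
draw_matchable_feature <- function(universe, n_peaks, seed, config) {
  for (attempt in 1:25) {
    idx <- withr::with_seed(seed + 1000L * attempt,
                            sample(nrow(universe$peaks), n_peaks))
    fs <- feature_set(idx, sprintf("f%d_%d", seed, attempt), nrow(universe$peaks))
    ok <- tryCatch({
      m <- prism:::build_matcher(universe$peaks, fs, config$gc_tolerance,
                                 config$accessibility_tolerance)
      prism:::matcher_fallback(m)  # certify a perfect assignment exists
      TRUE
    }, prism_error_unmatchable_peak = function(e) FALSE)
    if (ok) return(fs)
  }
  stop("no matchable feature set found in 25 attempts")
}

# Small universes reused across tests (memoised per session).
calibration_universe <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_null_universe(fixture_spec(seed = 42))
    cache
  }
})
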