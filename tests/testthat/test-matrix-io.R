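test_that("triplet files expand to dense counts in cell-by-peak orientation", {
  dir <- withr::local_tempdir()
  bed <- write_bed_file(file.path(dir, "p.bed"), rep("chr1", 3),
                        c(0L, 1000L, 2000L), c(500L, 1500L, 2500L))
  bc <- write_barcodes(file.path(dir, "b.tsv"), c("AAA", "CCC"))

  # 2 cells x 3 peaks on disk, entries (1,1)=2 and (2,3)=1
  mtx <- write_mtx(file.path(dir, "m.mtx"), 2, 3,
                   data.frame(i = c(1, 2), j = c(1, 3), x = c(2, 1)))
  b <- read_peak_matrix(mtx, bed, bc)
  expect_equal(unname(as.matrix(b$counts)), rbind(c(2, 0, 0), c(0, 0, 1)))
  expect_identical(rownames(b$counts), c("AAA", "CCC"))
  expect_identical(colnames(b$counts), b$peaks$peak_id)

  # empty triplet section: all-zero matrix of the declared shape
  mtx0 <- write_mtx(file.path(dir, "m0.mtx"), 2, 3, data.frame(i = integer(), j = integer(), x = integer()))
  b0 <- read_peak_matrix(mtx0, bed, bc)
  expect_equal(unname(as.matrix(b0$counts)), matrix(0, 2, 3))

  # 3 x 2 on disk (peaks as rows) is auto-transposed
  mtxT <- write_mtx(file.path(dir, "mt.mtx"), 3, 2,
                    data.frame(i = c(1, 3), j = c(1, 2), x = c(2, 1)))
  bT <- read_peak_matrix(mtxT, bed, bc)
  expect_equal(unname(as.matrix(bT$counts)), rbind(c(2, 0, 0), c(0, 0, 1)))
})

test_that("malformed bundles raise typed errors naming the sizes", {
  dir <- withr::local_tempdir()
  bed <- write_bed_file(file.path(dir, "p.bed"), rep("chr1", 3),
                        c(0L, 1000L, 2000L), c(500L, 1500L, 2500L))
  bc <- write_barcodes(file.path(dir, "b.tsv"), c("AAA", "CCC"))
  mtx <- write_mtx(file.path(dir, "bad.mtx"), 4, 3,
                   data.frame(i = 1, j = 1, x = 1))
  expect_error(read_peak_matrix(mtx, bed, bc), class = "prism_error_dimension_mismatch")
  expect_error(read_peak_matrix(mtx, bed, bc), "4 x 3.*3 peak.*2 barcode")

  bed_dup <- write_bed_file(file.path(dir, "dup.bed"), rep("chr1", 3),
                            c(0L, 0L, 2000L), c(500L, 500L, 2500L))
  mtx2 <- write_mtx(file.path(dir, "m2.mtx"), 2, 3, data.frame(i = 1, j = 1, x = 1))
  expect_error(read_peak_matrix(mtx2, bed_dup, bc), class = "prism_error_duplicate_peaks")

  # square ambiguous case demands an explicit orientation
  bed2 <- write_bed_file(file.path(dir, "p2.bed"), rep("chr1", 2), c(0L, 1000L), c(500L, 1500L))
  mtx3 <- write_mtx(file.path(dir, "sq.mtx"), 2, 2, data.frame(i = 1, j = 2, x = 3))
  expect_error(read_peak_matrix(mtx3, bed2, bc), class = "prism_error_ambiguous_orientation")
  sq <- read_peak_matrix(mtx3, bed2, bc, orientation = "peaks_by_cells")
  expect_equal(unname(as.matrix(sq$counts)), rbind(c(0, 0), c(3, 0)))
})

test_that("a written bundle reads back identically", {
  u <- generate_null_universe(fixture_spec(n_cells = 20, n_peaks = 50, seed = 7))
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(u, dir)
  b <- read_peak_matrix(paths["matrix"], paths["peaks"], paths["barcodes"])
  expect_equal(as.matrix(b$counts), as.matrix(u$binary))
  expect_identical(rownames(b$counts), rownames(u$binary))
  expect_identical(b$peaks$peak_id, u$peaks$peak_id)
})

test_that("gzipped sidecars and matrices are accepted", {
  u <- generate_null_universe(fixture_spec(n_cells = 10, n_peaks = 20, seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(u, dir)
  gz <- function(p) {
    out <- paste0(p, ".gz")
    con <- gzfile(out, "wb")
    writeLines(readLines(p), con)
    close(con)
    out
  }
  b <- read_peak_matrix(gz(paths["matrix"]), gz(paths["peaks"]), gz(paths["barcodes"]))
  expect_equal(as.matrix(b$counts), as.matrix(u$binary))
})

test_that("binarize thresholds counts and is idempotent", {
  counts <- rbind(c(2, 0), c(1, 3))
  b1 <- binarize(counts)
  expect_equal(unname(as.matrix(b1)), rbind(c(1, 0), c(1, 1)))
  expect_equal(unname(total_accessibility(b1)), c(1L, 2L))
  expect_equal(unname(as.matrix(binarize(counts, threshold = 2))), rbind(c(1, 0), c(0, 1)))
  expect_equal(unname(as.matrix(binarize(b1))), unname(as.matrix(b1)))
  expect_equal(unname(as.matrix(binarize(matrix(0, 2, 2)))), matrix(0, 2, 2))
  expect_error(binarize(rbind(c(-1, 0), c(0, 0))), class = "prism_error_bad_value")
})

test_that("mean accessibility is the per-peak fraction of accessible cells", {
  m <- Matrix::Matrix(cbind(c(1, 1, 0, 0), c(1, 1, 1, 1), c(1, 0, 0, 0)), sparse = TRUE)
  colnames(m) <- c("a", "b", "c")
  expect_equal(unname(mean_accessibility(m)), c(0.5, 1, 0.25))
})

test_that("feature mapping follows the half-open overlap convention", {
  peaks <- peak_table("chr1", 100L, 200L)
  included <- map_feature_to_peaks(peaks, tibble::tibble(chrom = "chr1", start = 150L, end = 300L))
  expect_equal(included$peak_indices, 1L)
  expect_error(
    map_feature_to_peaks(peaks, tibble::tibble(chrom = "chr1", start = 200L, end = 300L)),
    class = "prism_error_empty_feature_set"
  )
  expect_error(
    map_feature_to_peaks(peaks, tibble::tibble(chrom = "chr2", start = 100L, end = 200L)),
    class = "prism_error_empty_feature_set"
  )
})

test_that("feature mapping agrees with a brute-force all-pairs scan", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n_p <- sample(30:80, 1)
      starts <- sort(sample.int(5000, n_p)) * 10L
      peaks <- peak_table(sample(c("chr1", "chr2"), n_p, TRUE), starts,
                          starts + sample(50:300, n_p, TRUE))
      n_f <- sample(10:40, 1)
      fstart <- sample.int(50000, n_f)
      feats <- tibble::tibble(chrom = sample(c("chr1", "chr2"), n_f, TRUE),
                              start = fstart, end = fstart + sample(20:400, n_f, TRUE))
      minov <- sample(c(1L, 10L, 50L), 1)
      expected <- brute_force_overlap(peaks, feats, minov)
      got <- tryCatch(
        map_feature_to_peaks(peaks, feats, min_overlap_bp = minov)$peak_indices,
        prism_error_empty_feature_set = function(e) integer()
      )
      expect_equal(got, expected)
    }
  })
})
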