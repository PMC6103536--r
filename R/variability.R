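#' Angular cosine distance between two binary accessibility vectors
#'
#' The angle between the vectors, normalized by pi/2 so that identical
#' directions give 0 and orthogonal binary vectors (disjoint accessible
#' regions) give 1:
#' \deqn{d(a, b) = \frac{\arccos\left(\frac{a \cdot b}{\|a\|\|b\|}\right)}{\pi/2}}
#' The cosine is clamped to `[-1, 1]` before `arccos` to absorb floating-point
#' drift.
#'
#' @param a,b Numeric vectors of equal length, each with at least one nonzero
#'   entry.
#' @return A number in `[0, 1]` for binary inputs.
#' @export
cosine_distance <- function(a, b) {
  if (length(a) != length(b)) {
    prism_abort("Vectors must have the same length.", class = "prism_error_bad_value")
  }
  na2 <- sum(a * a)
  nb2 <- sum(b * b)
  if (na2 == 0 || nb2 == 0) stop_zero_vector()
  # one sqrt of the product: exact for integer-count vectors, so identical
  # vectors give cosine exactly 1 and distance exactly 0
  cs <- min(1, max(-1, sum(a * b) / sqrt(na2 * nb2)))
  acos(cs) / (pi / 2)
}

# Dense fast path: angular distance matrix for 0/1 rows (all rows nonzero).
angular_distance_matrix <- function(X) {
  C <- tcrossprod(X)
  nr2 <- diag(C)
  cs <- C / sqrt(outer(nr2, nr2))
  cs[cs > 1] <- 1
  cs[cs < -1] <- -1
  D <- acos(cs) / (pi / 2)
  diag(D) <- 0
  D
}

#' Pairwise angular cosine distances between cells at a peak subset
#'
#' Restricts the binary matrix to the feature's peaks, drops cells with no
#' accessible peak in the subset (their angle is undefined), and computes all
#' pairwise angular cosine distances.
#'
#' @param binary A 0/1 cells-by-peaks matrix.
#' @param feature A [feature_set()] (or bare integer vector of peak indices).
#' @return A list of class `prism_dist`: `d` (symmetric distance matrix with
#'   zero diagonal, entries in `[0, 1]`), `cell_ids`, and `dropped` (ids of
#'   all-zero cells removed).
#' @export
pairwise_distances <- function(binary, feature) {
  idx <- feature_indices(feature, ncol(binary))
  X <- as.matrix(binary[, idx, drop = FALSE])
  keep <- rowSums(X) > 0
  dropped <- rownames(binary)[!keep] %||% which(!keep)
  if (sum(keep) < 3L) stop_insufficient_cells(sum(keep))
  X <- X[keep, , drop = FALSE]
  D <- angular_distance_matrix(X)
  structure(
    list(d = D, cell_ids = rownames(binary)[keep] %||% which(keep), dropped = dropped),
    class = "prism_dist"
  )
}

feature_indices <- function(feature, n_universe) {
  idx <- if (inherits(feature, "prism_feature_set")) feature$peak_indices else as.integer(feature)
  if (length(idx) == 0L) stop_empty_feature_set(feature_name(feature))
  if (any(idx < 1L | idx > n_universe)) {
    prism_abort("Feature peak indices out of range for this matrix.",
                class = "prism_error_bad_value")
  }
  idx
}

feature_name <- function(feature) {
  if (inherits(feature, "prism_feature_set")) feature$name else "feature"
}

#' Principal-coordinate embedding of a distance matrix
#'
#' Classical multidimensional scaling: the elementwise-squared distances are
#' double-centered (Gower), `B = -1/2 J (D*D) J`, and `B` is eigendecomposed.
#' Coordinates are eigenvectors scaled by the square roots of their
#' eigenvalues; only eigenvalues above `eig_tol` times the largest are kept,
#' and negative eigenvalues (non-Euclidean distances) are dropped with their
#' relative mass reported. Eigenvector signs follow the convention that each
#' column's largest-magnitude entry is positive, so embeddings are
#' reproducible.
#'
#' @param D A symmetric distance matrix (or a `prism_dist`).
#' @param eig_tol Relative eigenvalue retention tolerance.
#' @return A list of class `prism_embedding`: `coords` (cells-by-k, centroid
#'   at the origin), `eigenvalues` (nonincreasing, positive), and
#'   `dropped_negative_mass` (sum of |negative eigenvalues| over sum of |all|).
#' @export
pcoa_embed <- function(D, eig_tol = 1e-9) {
  if (inherits(D, "prism_dist")) D <- D$d
  n <- nrow(D)
  D2 <- D * D
  rm_ <- rowMeans(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(D2))
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  total_mass <- sum(abs(ev))
  neg_mass <- if (total_mass > 0) sum(abs(ev[ev < 0])) / total_mass else 0
  keep <- ev > eig_tol * max(ev, 0)
  if (!any(keep)) {
    return(structure(
      list(coords = matrix(numeric(0), n, 0), eigenvalues = numeric(0),
           dropped_negative_mass = neg_mass),
      class = "prism_embedding"
    ))
  }
  V <- e$vectors[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude component positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  coords <- V %*% diag(sqrt(ev[keep]), sum(keep))
  structure(
    list(coords = coords, eigenvalues = ev[keep], dropped_negative_mass = neg_mass),
    class = "prism_embedding"
  )
}

# Internal hot path: mean distance to the centroid of the principal-coordinate
# embedding of the angular distance matrix of X (dense 0/1, zero rows allowed
# and dropped). Compiled kernel; returns a bare number.
dispersion_value <- function(X, eig_tol = 1e-9) {
  v <- dispersion_value_cpp(X, eig_tol)
  if (v < 0) stop_insufficient_cells(sum(rowSums(X) > 0))
  v
}

#' Raw (pre-correction) cell-to-cell variability of a peak subset
#'
#' The mean Euclidean distance of cells to their centroid in the
#' principal-coordinate embedding of the pairwise angular cosine distances.
#' After centering the centroid is the origin, so this is the mean coordinate
#' norm. Zero exactly when all used cells have identical accessibility
#' vectors.
#'
#' @inheritParams pairwise_distances
#' @return A list of class `prism_raw_variability`: `value`, `n_cells_used`,
#'   `n_cells_dropped_zero`.
#' @export
raw_variability <- function(binary, feature) {
  idx <- feature_indices(feature, ncol(binary))
  X <- as.matrix(binary[, idx, drop = FALSE])
  keep <- rowSums(X) > 0
  if (sum(keep) < 3L) stop_insufficient_cells(sum(keep))
  structure(
    list(
      value = dispersion_value(X),
      n_cells_used = sum(keep),
      n_cells_dropped_zero = sum(!keep)
    ),
    class = "prism_raw_variability"
  )
}

#' @export
print.prism_raw_variability <- function(x, ...) {
  cat(sprintf("<prism_raw_variability> %.6g (%d cells used, %d dropped)\n",
              x$value, x$n_cells_used, x$n_cells_dropped_zero))
  invisible(x)
}

#' Write a distance matrix and per-cell centroid distances as TSV
#'
#' @param dist A `prism_dist` from [pairwise_distances()].
#' @param path Output path for the distance matrix; per-cell centroid
#'   distances go to `paste0(path, ".centroid.tsv")`.
#' @return `path`, invisibly.
#' @export
write_distances <- function(dist, path) {
  d <- as.data.frame(dist$d)
  names(d) <- dist$cell_ids
  readr::write_tsv(tibble(cell_id = dist$cell_ids, d), path, progress = FALSE)
  emb <- pcoa_embed(dist)
  cd <- if (ncol(emb$coords)) sqrt(rowSums(emb$coords^2)) else rep(0, length(dist$cell_ids))
  readr::write_tsv(tibble(cell_id = dist$cell_ids, centroid_distance = cd),
                   paste0(path, ".centroid.tsv"), progress = FALSE)
  invisible(path)
}
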