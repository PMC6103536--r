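#' Configuration for the heterogeneity-titration benchmark
#'
#' Model 1 synthesizes heterogeneity with comparable total accessibility
#' between cells (GC-matched peaks drawn from the whole pool); model 2 draws
#' the matched peaks from the most accessible quartile, creating large
#' differences in total accessibility. Subtype A uses the cells with highest
#' total accessibility (ideal coverage), subtype B the lowest (noisy
#' coverage).
#'
#' @param model 1 or 2.
#' @param subtype `"A"` (highest-coverage cells) or `"B"` (lowest).
#' @param n_peaks Number of original peaks (default 500).
#' @param n_cells Number of cells entering the mixture (default 100).
#' @param n_steps Number of equally spaced mixture proportions (default 50,
#'   giving 2%, 4%, ..., 100%).
#' @param accessibility_percentile Percentile cut for model 2's matched-peak
#'   pool (default 75; matched peaks must lie strictly above it).
#' @param loess_span Span of the LOESS fit used for the curve MSE.
#' @param variability `"bias_corrected"` (default) or `"raw"`: the statistic
#'   plotted per proportion. The bias-corrected mode draws one set of
#'   background peak sets per run and reuses it across proportions (the
#'   divisor does not depend on the mixture).
#' @param n_background_iter Background sets for the bias-corrected mode.
#' @param gc_tolerance GC window for the matched block and backgrounds
#'   (default 0.05: at desk scale a 0.02 window leaves extreme-GC original
#'   peaks without enough one-to-one candidates in a ~2,000-peak universe).
#' @param accessibility_tolerance Accessibility window for background
#'   selection; `Inf` disables it (the matched block itself is always drawn
#'   GC-only, as in the benchmark design).
#' @param seed Master seed.
#' @return A `prism_simulation_config` list.
#' @export
simulation_config <- function(model = 1L, subtype = c("A", "B"), n_peaks = 500L,
                              n_cells = 100L, n_steps = 50L,
                              accessibility_percentile = 75,
                              loess_span = 0.75,
                              variability = c("bias_corrected", "raw"),
                              n_background_iter = 30L,
                              gc_tolerance = 0.05,
                              accessibility_tolerance = Inf,
                              seed = 1L) {
  subtype <- match.arg(subtype)
  variability <- match.arg(variability)
  if (!model %in% c(1L, 2L)) {
    prism_abort("`model` must be 1 or 2.", class = "prism_error_bad_value")
  }
  if (n_peaks < 2L || n_steps < 3L) {
    prism_abort("Need n_peaks >= 2 and n_steps >= 3.", class = "prism_error_bad_value")
  }
  structure(
    list(model = as.integer(model), subtype = subtype,
         n_peaks = as.integer(n_peaks), n_cells = as.integer(n_cells),
         n_steps = as.integer(n_steps),
         accessibility_percentile = accessibility_percentile,
         loess_span = loess_span, variability = variability,
         n_background_iter = as.integer(n_background_iter),
         gc_tolerance = gc_tolerance,
         accessibility_tolerance = accessibility_tolerance,
         seed = as.integer(seed)),
    class = "prism_simulation_config"
  )
}

#' Select cells by total accessibility
#'
#' Subtype A takes the `n_cells` cells with highest total accessibility,
#' subtype B the lowest; ties are broken by lexicographic cell id.
#'
#' @param binary A 0/1 cells-by-peaks matrix with rownames.
#' @param subtype `"A"` or `"B"`.
#' @param n_cells Number of cells to select.
#' @return Character vector of selected cell ids (or integer indices when the
#'   matrix has no rownames), in selection order.
#' @export
select_cells <- function(binary, subtype = c("A", "B"), n_cells) {
  subtype <- match.arg(subtype)
  if (n_cells > nrow(binary)) {
    prism_abort("`n_cells` exceeds the number of cells.", class = "prism_error_bad_value")
  }
  totals <- Matrix::rowSums(binary)
  ids <- rownames(binary) %||% as.character(seq_len(nrow(binary)))
  ord <- if (subtype == "A") order(-totals, ids) else order(totals, ids)
  sel <- ord[seq_len(n_cells)]
  if (is.null(rownames(binary))) sel else rownames(binary)[sel]
}

#' Draw the original and GC-matched peak blocks for one simulation
#'
#' The original block is a uniform draw of `n_peaks` peaks. The matched block
#' is a peak-for-peak GC-matched draw (same machinery as background
#' selection) from the full remaining pool (model 1) or from the peaks
#' strictly above the universe's `accessibility_percentile` in mean
#' accessibility (model 2); it is always disjoint from the original block.
#'
#' @param peaks Annotated [peak_table()].
#' @param config A [simulation_config()].
#' @return A list with [feature_set()]s `original` and `matched`.
#' @export
draw_peak_blocks <- function(peaks, config) {
  n_univ <- nrow(peaks)
  annotated <- which(!is.na(peaks$gc) & !is.na(peaks$mean_accessibility))
  orig_idx <- with_stream(config$seed, "original_block",
                          code = sort(annotated[sample.int(length(annotated), config$n_peaks)]))
  original <- feature_set(orig_idx, name = "original", n_universe = n_univ)
  pool_restrict <- if (config$model == 2L) {
    cut <- stats::quantile(peaks$mean_accessibility[annotated],
                           config$accessibility_percentile / 100, na.rm = TRUE)
    which(peaks$mean_accessibility > cut)
  } else {
    NULL
  }
  m <- build_matcher(peaks, original, config$gc_tolerance,
                     accessibility_tolerance = Inf, pool_restrict = pool_restrict)
  matched_idx <- with_stream(config$seed, "matched_block", code = matcher_draw(m))
  # order preserved: matched peak k is GC-matched to original peak k, so the
  # mixture aligns the blocks position-by-position
  list(
    original = original,
    matched = feature_set(matched_idx, name = "matched", n_universe = n_univ)
  )
}

#' Build the mixture matrix at one proportion
#'
#' The first `round(p * n_cells)` cells (in the given cell order) contribute
#' their accessibility at the original peaks; the remaining cells contribute
#' their accessibility at the matched peaks, aligned position-by-position, so
#' the result is always `n_cells x n_peaks`. Peaks are mixed rather than
#' cells so that cell identities (and per-cell technical quality) are
#' unchanged across the titration.
#'
#' @param binary A 0/1 cells-by-peaks matrix.
#' @param cells Cell ids (or indices) in mixture order.
#' @param original,matched [feature_set()]s of equal size.
#' @param p Mixture proportion in `[0, 1]` (fraction of cells on original
#'   peaks).
#' @return A dense 0/1 `length(cells) x n_peaks` matrix.
#' @export
build_mixture <- function(binary, cells, original, matched, p) {
  if (p < 0 || p > 1) {
    prism_abort("`p` must lie in [0, 1].", class = "prism_error_bad_value")
  }
  oi <- feature_indices(original, ncol(binary))
  mi <- feature_indices(matched, ncol(binary))
  if (length(oi) != length(mi)) {
    prism_abort("Original and matched blocks must have equal size.",
                class = "prism_error_bad_value")
  }
  n <- length(cells)
  k <- round(p * n)
  Xo <- as.matrix(binary[cells, oi, drop = FALSE])
  Xm <- as.matrix(binary[cells, mi, drop = FALSE])
  out <- Xm
  if (k > 0) out[seq_len(k), ] <- Xo[seq_len(k), , drop = FALSE]
  dimnames(out) <- list(rownames(Xo), paste0("mix_", seq_along(oi)))
  out
}

#' Run a heterogeneity titration
#'
#' For each of `n_steps` equally spaced proportions in (0, 1], builds the
#' peak-block mixture and computes the variability (raw, or bias-corrected
#' against GC-matched background sets computed on the unmixed matrix), then
#' scores the curve with the concavity [u_statistic()] and [loess_mse()].
#'
#' @param binary A 0/1 cells-by-peaks matrix.
#' @param peaks Annotated [peak_table()].
#' @param config A [simulation_config()].
#' @return A `prism_titration` object: tibble accessor via [tidy()], summary
#'   via [glance()], curve plot via [autoplot()].
#' @export
run_titration <- function(binary, peaks, config = simulation_config()) {
  blocks <- draw_peak_blocks(peaks, config)
  cells <- select_cells(binary, config$subtype, config$n_cells)
  proportions <- seq_len(config$n_steps) / config$n_steps
  values <- vapply(proportions, function(p) {
    dispersion_value(build_mixture(binary, cells, blocks$original, blocks$matched, p))
  }, numeric(1))
  if (config$variability == "bias_corrected") {
    m <- build_matcher(peaks, blocks$original, config$gc_tolerance,
                       config$accessibility_tolerance,
                       pool_restrict = setdiff(seq_len(nrow(peaks)),
                                               blocks$matched$peak_indices))
    bg <- vapply(seq_len(config$n_background_iter), function(i) {
      idx <- with_stream(config$seed, "titration_bg", i, code = matcher_draw(m))
      dispersion_value(as.matrix(binary[cells, idx, drop = FALSE]))
    }, numeric(1))
    if (mean(bg) == 0) stop_degenerate_background()
    values <- values / mean(bg)
  }
  structure(
    list(
      proportions = proportions,
      variability = values,
      u_statistic = u_statistic(values),
      loess_mse = loess_mse(proportions, values, span = config$loess_span),
      blocks = blocks,
      cells = cells,
      config = config
    ),
    class = "prism_titration"
  )
}

#' @export
print.prism_titration <- function(x, ...) {
  cat(sprintf(
    "<prism_titration> model %d subtype %s: %d steps, U = %.3f, LOESS MSE = %.3g\n",
    x$config$model, x$config$subtype, length(x$proportions),
    x$u_statistic, x$loess_mse
  ))
  invisible(x)
}

#' Tidy a titration curve
#'
#' @param x A `prism_titration`.
#' @param ... Unused.
#' @return Tibble with columns `proportion`, `variability`.
#' @method tidy prism_titration
#' @export
tidy.prism_titration <- function(x, ...) {
  tibble(proportion = x$proportions, variability = x$variability)
}

#' @rdname tidy.prism_titration
#' @method glance prism_titration
#' @export
glance.prism_titration <- function(x, ...) {
  tibble(
    model = x$config$model, subtype = x$config$subtype,
    n_peaks = x$config$n_peaks, n_cells = x$config$n_cells,
    n_steps = x$config$n_steps,
    u_statistic = x$u_statistic, loess_mse = x$loess_mse,
    argmax_proportion = x$proportions[which.max(x$variability)],
    seed = x$config$seed
  )
}

#' Titration curve plot
#'
#' @param object A `prism_titration`.
#' @param ... Unused.
#' @return A ggplot of variability against mixture proportion with a LOESS
#'   smooth.
#' @method autoplot prism_titration
#' @export
autoplot.prism_titration <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$proportion, y = .data$variability)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x,
                         span = object$config$loess_span, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "proportion of cells on original peaks",
      y = "variability",
      title = sprintf("model %d subtype %s: U = %.3f, LOESS MSE = %.2g",
                      object$config$model, object$config$subtype,
                      object$u_statistic, object$loess_mse)
    )
}

#' Concavity (U) statistic of a titration curve
#'
#' Successive differences of the variability curve are rank-correlated
#' (Spearman, midranks for ties) with the decreasing sequence
#' `m-1, m-2, ..., 1` — for the standard 50-point curve, the sequence 49
#' through 1. A perfectly concave (inverse-U) curve, whose slope decreases
#' continuously, scores 1; a convex curve scores -1. Returns `NA` when all
#' differences are tied (e.g. an exactly linear curve).
#'
#' @param variability Numeric vector of curve values (length at least 3).
#' @return A number in `[-1, 1]`, or `NA`.
#' @export
u_statistic <- function(variability) {
  m <- length(variability)
  if (m < 3L) {
    prism_abort("Need at least 3 curve points.", class = "prism_error_bad_value")
  }
  d <- diff(variability)
  if (diff(range(d)) <= 1e-12 * max(abs(d), 1)) return(NA_real_)
  cor(d, rev(seq_len(m - 1L)), method = "spearman")
}

#' Mean squared error around a LOESS fit
#'
#' Local quadratic regression (tricube weights) of variability on proportion;
#' the returned value is the mean squared residual at the observed points — a
#' measure of how noisy the curve is around its own smooth trend.
#'
#' @param proportions,variability Numeric vectors of equal length (at least
#'   5 points).
#' @param span LOESS span (default 0.75).
#' @return Non-negative number.
#' @export
loess_mse <- function(proportions, variability, span = 0.75) {
  if (length(proportions) < 5L) {
    prism_abort("Need at least 5 curve points for a LOESS fit.",
                class = "prism_error_bad_value")
  }
  fit <- stats::loess(variability ~ proportions, span = span, degree = 2,
                      surface = "direct",
                      control = stats::loess.control(statistics = "none"))
  mean(stats::residuals(fit)^2)
}
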