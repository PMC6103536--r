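#' Configuration for background matching and negative controls
#'
#' @param n_background_iter Number of matched background peak sets per
#'   variability (default 30, as used for the published analyses).
#' @param n_negative_control Number of random negative-control peak sets
#'   (default 30).
#' @param gc_tolerance Maximum absolute GC difference between an original peak
#'   and its matched background peak (default 0.02).
#' @param accessibility_tolerance Maximum absolute difference between a
#'   background peak's mean accessibility and the overall mean accessibility
#'   of the original peak set (default 0.01).
#' @param seed Master seed; every resampling stage derives its own stream from
#'   it, so changing an iteration count never shifts earlier draws.
#' @return A `prism_background_config` list.
#' @export
background_config <- function(n_background_iter = 30L, n_negative_control = 30L,
                              gc_tolerance = 0.02, accessibility_tolerance = 0.01,
                              seed = 1L) {
  if (n_background_iter < 1L || n_negative_control < 1L) {
    prism_abort("Iteration counts must be at least 1.", class = "prism_error_bad_value")
  }
  if (gc_tolerance <= 0 || accessibility_tolerance <= 0) {
    prism_abort("Tolerances must be positive.", class = "prism_error_bad_value")
  }
  structure(
    list(
      n_background_iter = as.integer(n_background_iter),
      n_negative_control = as.integer(n_negative_control),
      gc_tolerance = gc_tolerance,
      accessibility_tolerance = accessibility_tolerance,
      seed = as.integer(seed)
    ),
    class = "prism_background_config"
  )
}

# Matching machinery ----------------------------------------------------------
#
# Candidates for each original peak are the non-feature peaks with non-missing
# annotations whose GC lies within gc_tolerance of that peak's GC and (when
# the accessibility window applies) whose mean accessibility lies within
# accessibility_tolerance of the feature set's overall mean accessibility.
# Because the pool is sorted by GC, each candidate set is a contiguous index
# range. One background set needs a distinct candidate per original peak
# (sampling without replacement), which is an assignment problem: a
# randomized rarest-first greedy pass almost always succeeds; a maximum
# bipartite matching (Hopcroft-Karp via igraph) certifies feasibility and
# serves as deterministic fallback.

build_matcher <- function(peaks, feature, gc_tolerance, accessibility_tolerance,
                          pool_restrict = NULL) {
  idx <- feature_indices(feature, nrow(peaks))
  pool <- setdiff(pool_restrict %||% seq_len(nrow(peaks)), idx)
  pool <- pool[!is.na(peaks$gc[pool]) & !is.na(peaks$mean_accessibility[pool])]
  if (is.finite(accessibility_tolerance)) {
    target <- mean(peaks$mean_accessibility[idx])
    pool <- pool[abs(peaks$mean_accessibility[pool] - target) <= accessibility_tolerance]
  }
  feat_gc <- peaks$gc[idx]
  if (anyNA(feat_gc)) {
    prism_abort("Feature peaks must have non-missing GC for background matching.",
                class = "prism_error_bad_value")
  }
  pg_order <- order(peaks$gc[pool])
  pool <- pool[pg_order]
  pg <- peaks$gc[pool]
  lo <- findInterval(feat_gc - gc_tolerance, pg, left.open = TRUE) + 1L
  hi <- findInterval(feat_gc + gc_tolerance, pg)
  n_cand <- hi - lo + 1L
  if (length(pool) == 0L || any(n_cand <= 0L)) {
    bad <- if (length(pool) == 0L) seq_along(idx) else which(n_cand <= 0L)
    stop_unmatchable(peaks$peak_id[idx[bad]], feat_gc[bad])
  }
  m <- list(pool = pool, lo = lo, hi = hi, n_cand = n_cand, m = length(idx),
            order0 = order(n_cand), feature_ids = peaks$peak_id[idx], feat_gc = feat_gc,
            cache = new.env(parent = emptyenv()))
  if (sum(n_cand) < length(idx)) matcher_fallback(m)  # cheap early infeasibility
  m
}

# Certification is lazy: computed (and cached) only when the greedy sampler
# dead-ends, which is rare on well-provisioned pools.
matcher_fallback <- function(m) {
  if (is.null(m$cache$fallback)) m$cache$fallback <- matcher_certify(m)
  m$cache$fallback
}

# Maximum bipartite matching; errors (typed) when no perfect assignment exists.
matcher_certify <- function(m) {
  el <- cbind(
    rep(seq_len(m$m), m$n_cand),
    m$m + unlist(lapply(seq_len(m$m), function(k) m$lo[k]:m$hi[k]))
  )
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$type <- seq_len(igraph::vcount(g)) > m$m
  mm <- igraph::max_bipartite_match(g)
  if (mm$matching_size < m$m) {
    # identify hard peaks: those left unmatched
    unmatched <- which(is.na(mm$matching[seq_len(m$m)]))
    stop_unmatchable(m$feature_ids[unmatched], m$feat_gc[unmatched])
  }
  m$pool[mm$matching[seq_len(m$m)] - m$m]
}

matcher_draw <- function(m, tries = 20L) {
  for (t in seq_len(tries)) {
    used <- logical(length(m$pool))
    chosen <- integer(m$m)
    ok <- TRUE
    for (k in m$order0) {
      cand <- m$lo[k]:m$hi[k]
      avail <- cand[!used[cand]]
      if (!length(avail)) { ok <- FALSE; break }
      pick <- if (length(avail) == 1L) avail else avail[sample.int(length(avail), 1L)]
      chosen[k] <- pick
      used[pick] <- TRUE
    }
    if (ok) return(m$pool[chosen])
  }
  matcher_fallback(m)
}

#' Sample one GC- and accessibility-matched background peak set
#'
#' Draws, for each peak of the feature set, one background peak from the
#' non-feature pool with `|gc_bg - gc_orig| <= gc_tolerance` and mean
#' accessibility within `accessibility_tolerance` of the feature set's overall
#' mean accessibility, without replacement, so the background set has the same
#' cardinality as the feature set and is disjoint from it.
#'
#' @param peaks Annotated [peak_table()] (`gc` and `mean_accessibility` filled).
#' @param feature A [feature_set()].
#' @param config A [background_config()]; `config$seed` drives the draw.
#' @param iteration Integer label of the iteration (its seed stream).
#' @return A [feature_set()] of background peak indices.
#' @export
sample_background_set <- function(peaks, feature, config = background_config(),
                                  iteration = 1L) {
  m <- build_matcher(peaks, feature, config$gc_tolerance, config$accessibility_tolerance)
  idx <- with_stream(config$seed, "background", feature_name(feature), iteration,
                     code = matcher_draw(m))
  # order preserved: element k is the background peak matched to feature peak k
  feature_set(idx, name = paste0(feature_name(feature), "_bg", iteration),
              n_universe = nrow(peaks))
}

# Raw variability of a column subset, via the dense fast path.
raw_value_of <- function(binary, idx) {
  dispersion_value(as.matrix(binary[, idx, drop = FALSE]))
}

#' Bias-corrected variation of a feature peak set
#'
#' Raw variability of the feature divided by the mean raw variability of
#' matched background peak sets.
#'
#' @param binary A 0/1 cells-by-peaks matrix.
#' @param feature A [feature_set()].
#' @param peaks Annotated [peak_table()] aligned with `binary`'s columns.
#' @param config A [background_config()].
#' @return A list: `bias_corrected`, `raw`, `background_raws`
#'   (length `n_background_iter`).
#' @export
bias_corrected_variation <- function(binary, feature, peaks, config = background_config()) {
  raw <- raw_value_of(binary, feature_indices(feature, ncol(binary)))
  m <- build_matcher(peaks, feature, config$gc_tolerance, config$accessibility_tolerance)
  background_raws <- vapply(seq_len(config$n_background_iter), function(i) {
    idx <- with_stream(config$seed, "background", feature_name(feature), i,
                       code = matcher_draw(m))
    raw_value_of(binary, idx)
  }, numeric(1))
  bg_mean <- mean(background_raws)
  if (bg_mean == 0) stop_degenerate_background()
  list(bias_corrected = raw / bg_mean, raw = raw, background_raws = background_raws)
}

#' Final (negative-control-normalized) variation with Z-score and p-value
#'
#' Runs the full two-stage normalization: the feature's bias-corrected
#' variation (raw over mean matched-background variability) is divided by the
#' mean bias-corrected variation of random negative-control peak sets of the
#' same size, each itself background-normalized for its own GC content. The
#' negative controls also yield a Z-score, an empirical upper-tail p-value
#' with add-one smoothing, and a normal-theory p-value from the Z-score.
#'
#' A value of 1 means the feature is associated with no more variation than
#' negative control; above 1, more; below 1, less.
#'
#' Negative-control draws that cannot be background-matched at the configured
#' tolerances are redrawn from a deterministic seed stream (bounded attempts);
#' overlap between different control sets is permitted.
#'
#' @inheritParams bias_corrected_variation
#' @param feature_name Optional label overriding the feature set's name.
#' @return A `prism_variability` object; see [tidy.prism_variability()].
#' @export
final_variation <- function(binary, feature, peaks, config = background_config(),
                            feature_name = NULL) {
  fname <- feature_name %||% feature_name(feature)
  fv <- bias_corrected_variation(binary, feature, peaks, config)
  nonfeat <- setdiff(seq_len(nrow(peaks)), feature_indices(feature, ncol(binary)))
  nonfeat <- nonfeat[!is.na(peaks$gc[nonfeat]) & !is.na(peaks$mean_accessibility[nonfeat])]
  n_feat <- length(feature_indices(feature, ncol(binary)))
  if (length(nonfeat) < n_feat) {
    prism_abort("Too few non-feature peaks to draw negative controls.",
                class = "prism_error_bad_value")
  }
  n_ctrl <- config$n_negative_control
  max_attempts <- n_ctrl * 10L  # unmatchable draws are common only when the
  # pool is tight; attempt-indexed seed streams keep successful draws stable
  ctrl_bc <- numeric(n_ctrl)
  ctrl_raws <- numeric(n_ctrl)
  got <- 0L
  attempt <- 0L
  while (got < n_ctrl && attempt < max_attempts) {
    attempt <- attempt + 1L
    ctrl_idx <- with_stream(config$seed, "control", fname, attempt,
                            code = nonfeat[sample.int(length(nonfeat), n_feat)])
    ctrl <- feature_set(ctrl_idx, name = paste0(fname, "_ctrl", attempt),
                        n_universe = nrow(peaks))
    cv <- tryCatch(
      bias_corrected_variation(binary, ctrl, peaks, config),
      prism_error_unmatchable_peak = function(e) NULL
    )
    if (is.null(cv)) next
    got <- got + 1L
    ctrl_bc[got] <- cv$bias_corrected
    ctrl_raws[got] <- cv$raw
  }
  if (got < n_ctrl) {
    prism_abort(
      sprintf("Could only background-match %d of %d negative-control sets.", got, n_ctrl),
      class = "prism_error_unmatchable_peak"
    )
  }
  ctrl_mean <- mean(ctrl_bc)
  ctrl_sd <- sd(ctrl_bc)
  z <- if (!is.na(ctrl_sd) && ctrl_sd > 0) (fv$bias_corrected - ctrl_mean) / ctrl_sd else NA_real_
  p_emp <- (1 + sum(ctrl_bc >= fv$bias_corrected)) / (n_ctrl + 1)
  p_norm <- if (is.na(z)) NA_real_ else stats::pnorm(z, lower.tail = FALSE)
  structure(
    list(
      feature_name = fname,
      raw = fv$raw,
      background_mean = mean(fv$background_raws),
      bias_corrected = fv$bias_corrected,
      negative_control_mean = ctrl_mean,
      final = fv$bias_corrected / ctrl_mean,
      z_score = z,
      p_value = p_emp,
      p_value_normal = p_norm,
      background_raws = fv$background_raws,
      control_bias_corrected = ctrl_bc,
      control_raws = ctrl_raws,
      n_control_redraws = attempt - got,
      config = config
    ),
    class = "prism_variability"
  )
}

#' @export
print.prism_variability <- function(x, ...) {
  cat(sprintf(
    "<prism_variability> '%s'\n  raw %.4g | bias-corrected %.4g | final %.4g\n  z %.3g, empirical p %.3g (%d backgrounds, %d controls)\n",
    x$feature_name, x$raw, x$bias_corrected, x$final,
    x$z_score, x$p_value, x$config$n_background_iter, x$config$n_negative_control
  ))
  invisible(x)
}

#' Tidy a variability result
#'
#' @param x A `prism_variability` object.
#' @param ... Unused.
#' @return One-row tibble with the headline statistics.
#' @method tidy prism_variability
#' @export
tidy.prism_variability <- function(x, ...) {
  tibble(
    feature_name = x$feature_name,
    raw = x$raw,
    background_mean = x$background_mean,
    bias_corrected = x$bias_corrected,
    negative_control_mean = x$negative_control_mean,
    final = x$final,
    z_score = x$z_score,
    p_value = x$p_value,
    p_value_normal = x$p_value_normal
  )
}

#' @rdname tidy.prism_variability
#' @method glance prism_variability
#' @export
glance.prism_variability <- function(x, ...) {
  tibble(
    n_background_iter = x$config$n_background_iter,
    n_negative_control = x$config$n_negative_control,
    gc_tolerance = x$config$gc_tolerance,
    accessibility_tolerance = x$config$accessibility_tolerance,
    seed = x$config$seed,
    n_control_redraws = x$n_control_redraws
  )
}

#' Distribution plot of a variability result
#'
#' Shows the bias-corrected variations of the negative controls as a
#' histogram with the feature's bias-corrected variation marked.
#'
#' @param object A `prism_variability`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prism_variability
#' @export
autoplot.prism_variability <- function(object, ...) {
  df <- tibble(control = object$control_bias_corrected)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$control)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$bias_corrected, colour = "firebrick") +
    ggplot2::labs(
      x = "bias-corrected variation (negative controls)",
      y = "count",
      title = sprintf("%s: final variation %.3f (empirical p %.3g)",
                      object$feature_name, object$final, object$p_value)
    )
}
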