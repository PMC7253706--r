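# First-order histogram radiomics: 15 statistics per ROI, cohort feature
# matrix assembly, leakage-free standardization.

# Fixed statistic order; feature indices are stable across runs.
FIRST_ORDER_STATS <- c("mean", "median", "minimum", "maximum", "range",
                       "sd", "variance", "mad", "iqr", "rms", "energy",
                       "skewness", "kurtosis", "uniformity", "entropy")

#' First-order histogram statistics of a voxel-intensity sample
#'
#' Computes the 15 first-order radiomics statistics of a region's
#' grey-matter values: mean, median, minimum, maximum, range, standard
#' deviation, variance, mean absolute deviation, interquartile range, root
#' mean square, energy (sum of squares), skewness, kurtosis, uniformity and
#' entropy. Moments use the population convention (divisor n); kurtosis is
#' non-excess (a normal sample tends to 3). Uniformity and entropy are
#' computed from the probabilities p of an `n_bins` equal-width histogram
#' spanning the sample's own \[min, max\]: entropy = -sum p log2 p,
#' uniformity = sum p^2. A constant sample has one occupied bin
#' (uniformity 1, entropy 0) and undefined skewness/kurtosis, returned as 0
#' with a `degenerate` attribute.
#'
#' @param values Numeric vector of at least 2 voxel intensities.
#' @param n_bins Histogram bin count, default 64.
#' @return Named numeric vector of length 15 in fixed order.
#' @export
first_order_stats <- function(values, n_bins = 64L) {
  if (length(values) < 2L) stop("need at least 2 voxels")
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  mu <- mean(values)
  dev <- values - mu
  pop_var <- mean(dev^2)
  degenerate <- pop_var <= 0

  if (degenerate) {
    skew <- 0
    kurt <- 0
    p <- 1
  } else {
    skew <- mean(dev^3) / pop_var^1.5
    kurt <- mean(dev^4) / pop_var^2
    breaks <- seq(min(values), max(values), length.out = n_bins + 1L)
    counts <- tabulate(pmin(findInterval(values, breaks,
                                         rightmost.closed = TRUE),
                            n_bins), nbins = n_bins)
    p <- counts / n
    p <- p[p > 0]
  }

  out <- c(mean = mu,
           median = stats::median(values),
           minimum = min(values),
           maximum = max(values),
           range = max(values) - min(values),
           sd = sqrt(pop_var),
           variance = pop_var,
           mad = mean(abs(dev)),
           iqr = unname(stats::quantile(values, 0.75) -
                          stats::quantile(values, 0.25)),
           rms = sqrt(mean(values^2)),
           energy = sum(values^2),
           skewness = skew,
           kurtosis = kurt,
           uniformity = sum(p^2),
           entropy = -sum(p * log2(p)))
  attr(out, "degenerate") <- degenerate
  out
}

#' Extract the per-subject radiomic feature vector
#'
#' Concatenates the 15 first-order statistics of every ROI, in fixed ROI
#' order (by `roi_id`) then fixed statistic order, giving a vector of length
#' 15 x |ROIs| with deterministic names `ROI<id>_<statistic>`.
#'
#' @param map A [gm_map()] on the ROI grid.
#' @param rois An `roi_set` from [threshold_clusters()].
#' @param n_bins Histogram bin count passed to [first_order_stats()].
#' @return Named numeric vector of length `15 * length(rois$rois)`.
#' @export
extract_features <- function(map, rois, n_bins = 64L) {
  stopifnot(inherits(map, "gm_map"), inherits(rois, "roi_set"))
  order_ids <- order(vapply(rois$rois, `[[`, numeric(1L), "roi_id"))
  feats <- lapply(rois$rois[order_ids], function(r) {
    vals <- map$values[r$mask]
    if (length(vals) < 2L)
      stop(sprintf("ROI %d has fewer than 2 in-map voxels", r$roi_id))
    st <- first_order_stats(vals, n_bins)
    names(st) <- sprintf("ROI%02d_%s", r$roi_id, FIRST_ORDER_STATS)
    st
  })
  unlist(feats)
}

#' Assemble the cohort feature matrix
#'
#' @param maps List of [gm_map()].
#' @param rois An `roi_set`.
#' @param n_bins Histogram bin count.
#' @return Numeric matrix, rows = subjects (named by id, in sorted id order
#'   so assembly is invariant to input order), columns = named features.
#' @export
feature_matrix <- function(maps, rois, n_bins = 64L) {
  ids <- vapply(maps, function(m) m$subject_id, character(1L))
  o <- order(ids)
  X <- t(vapply(maps[o], extract_features, rois = rois, n_bins = n_bins,
                FUN.VALUE = numeric(15L * length(rois$rois))))
  rownames(X) <- ids[o]
  X
}

#' Fit standardization parameters on training data only
#'
#' Column means and sample standard deviations (divisor n-1) estimated on the
#' training matrix; validation data must be transformed with these training
#' parameters, never refitted, to preserve independence. Zero-variance
#' training columns are dropped (with a warning).
#'
#' @param train_matrix Numeric training feature matrix (>= 2 rows).
#' @return A `standardizer` list with `mean`, `sd` and `features`.
#' @export
fit_standardizer <- function(train_matrix) {
  if (nrow(train_matrix) < 2L) stop("need at least 2 training rows")
  mu <- colMeans(train_matrix)
  sd_ <- apply(train_matrix, 2L, stats::sd)
  keep <- sd_ > 0
  if (any(!keep))
    warning(sprintf("dropping %d zero-variance feature(s): %s", sum(!keep),
                    paste(utils::head(colnames(train_matrix)[!keep], 5L),
                          collapse = ", ")),
            call. = FALSE)
  structure(list(mean = mu[keep], sd = sd_[keep],
                 features = colnames(train_matrix)[keep]),
            class = "standardizer")
}

#' Apply fitted standardization parameters
#'
#' @param X Numeric feature matrix containing the standardizer's features.
#' @param params A `standardizer` from [fit_standardizer()].
#' @return The centred and scaled matrix, restricted to retained features.
#' @export
apply_standardizer <- function(X, params) {
  stopifnot(inherits(params, "standardizer"))
  missing_cols <- setdiff(params$features, colnames(X))
  if (length(missing_cols) > 0L)
    stop("matrix lacks feature(s): ", paste(utils::head(missing_cols, 5L),
                                            collapse = ", "))
  X <- X[, params$features, drop = FALSE]
  sweep(sweep(X, 2L, params$mean), 2L, params$sd, `/`)
}
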