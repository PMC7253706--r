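# Independent oracles and small fixture builders used across the suite.

# Brute-force flood fill: recursive frontier growth scanning ALL voxel pairs
# per step. Deliberately naive and independent of label_components().
oracle_flood_fill <- function(mask, connectivity) {
  d <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0L) return(integer(0L))
  adjacent <- function(a, b) {
    dv <- abs(a - b)
    if (any(dv > 1L)) return(FALSE)
    s <- sum(dv)
    if (connectivity == 6L) s == 1L
    else if (connectivity == 18L) s >= 1L && s <= 2L
    else s >= 1L
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    comp[s] <- cur
    repeat {
      grew <- FALSE
      for (a in which(comp == cur)) {
        for (b in which(comp == 0L)) {
          if (adjacent(coords[a, ], coords[b, ])) {
            comp[b] <- cur
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
  }
  # return sorted component sizes (labels are arbitrary)
  sort(tabulate(comp), decreasing = TRUE)
}

# Brute-force first-order statistics straight from the definitions.
oracle_first_order <- function(x, n_bins = 64L) {
  n <- length(x)
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / n
  counts <- integer(n_bins)
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    w <- (hi - lo) / n_bins
    for (xi in x) {
      b <- min(n_bins, floor((xi - lo) / w) + 1L)
      counts[b] <- counts[b] + 1L
    }
  } else counts[1L] <- n
  p <- counts[counts > 0] / n
  c(mean = mu,
    median = median(x),
    minimum = lo, maximum = hi, range = hi - lo,
    sd = sqrt(v), variance = v,
    mad = sum(abs(x - mu)) / n,
    iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    rms = sqrt(sum(x^2) / n),
    energy = sum(x^2),
    skewness = if (v > 0) (sum((x - mu)^3) / n) / v^1.5 else 0,
    kurtosis = if (v > 0) (sum((x - mu)^4) / n) / v^2 else 0,
    uniformity = sum(p^2),
    entropy = -sum(p * log2(p)))
}

# Exhaustive pairwise AUC: P(s+ > s-) + P(tie)/2.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Leave-one-out jackknife variance of the AUC.
oracle_jackknife_auc_var <- function(scores, labels) {
  n <- length(scores)
  th <- vapply(seq_len(n), function(i)
    oracle_auc_pairs(scores[-i], labels[-i]), numeric(1L))
  (n - 1) / n * sum((th - mean(th))^2)
}

# Stratified bootstrap p-value for an AUC difference (paired or unpaired),
# from the normal approximation on the bootstrap SD of the difference.
oracle_bootstrap_delong_p <- function(scores_a, labels_a, scores_b, labels_b,
                                      paired, B = 2000L, seed = 42L) {
  set.seed(seed)
  obs <- oracle_auc_pairs(scores_a, labels_a) -
    oracle_auc_pairs(scores_b, labels_b)
  diffs <- numeric(B)
  pos_a <- which(labels_a); neg_a <- which(!labels_a)
  pos_b <- which(labels_b); neg_b <- which(!labels_b)
  for (b in seq_len(B)) {
    ia <- c(sample(pos_a, replace = TRUE), sample(neg_a, replace = TRUE))
    ib <- if (paired) ia
          else c(sample(pos_b, replace = TRUE), sample(neg_b, replace = TRUE))
    diffs[b] <- oracle_auc_pairs(scores_a[ia], labels_a[ia]) -
      oracle_auc_pairs(scores_b[ib], labels_b[ib])
  }
  2 * pnorm(-abs(obs) / sd(diffs))
}

# VIF from a directly fitted auxiliary regression via lm().
oracle_vif <- function(design, j) {
  df <- as.data.frame(design)
  names(df) <- paste0("v", seq_len(ncol(df)))
  fml <- stats::as.formula(paste0("v", j, " ~ ",
                                  paste0("v", setdiff(seq_len(ncol(df)), j),
                                         collapse = " + ")))
  1 / (1 - summary(stats::lm(fml, data = df))$r.squared)
}

# A tiny labelled map cohort with a planted mean shift in given voxels.
make_toy_maps <- function(n1, n2, grid = c(10L, 10L, 10L), shift_idx = NULL,
                          shift = 0, sd = 1, seed = 1L) {
  set.seed(seed)
  maps <- vector("list", n1 + n2)
  for (s in seq_len(n1 + n2)) {
    v <- array(abs(rnorm(prod(grid), mean = 5, sd = sd)), grid)
    if (s <= n1 && !is.null(shift_idx)) v[shift_idx] <- v[shift_idx] + shift
    maps[[s]] <- gm_map(v, diag(4), sprintf("T%02d", s))
  }
  labels <- data.frame(
    subject_id = sprintf("T%02d", seq_len(n1 + n2)),
    pct_reduction = c(rep(80, n1), rep(40, n2)),
    label = rep(c("responder", "nonresponder"), c(n1, n2)),
    stringsAsFactors = FALSE)
  list(maps = maps, labels = labels)
}

# An roi_set wrapping explicit masks (for feature-extraction tests).
make_roi_set <- function(masks) {
  rois <- lapply(seq_along(masks), function(i)
    list(roi_id = i, mask = masks[[i]], size = sum(masks[[i]]),
         sign = 1L, peak_t = NA_real_, atlas_label = NA_character_,
         overlap_fraction = NA_real_))
  structure(list(rois = rois, df = NA_integer_, p_threshold = 0.05,
                 extent_threshold = 1L, connectivity = 18L),
            class = "roi_set")
}

# A t_stat_map with prescribed t values (mask = finite entries).
make_tmap <- function(t_values, df, p_threshold = 0.05, extent = 100L) {
  structure(list(t_values = t_values, df = df,
                 analysis_mask = !is.na(t_values),
                 p_threshold = p_threshold,
                 extent_threshold = as.integer(extent), n_dropped = 0L),
            class = "t_stat_map")
}

# Gaussian feature matrix with optional informative columns.
make_feature_matrix <- function(n1, n2, p, n_info = 0L, delta = 0, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm((n1 + n2) * p), n1 + n2, p,
              dimnames = list(sprintf("F%02d", seq_len(n1 + n2)),
                              sprintf("feat_%03d", seq_len(p))))
  if (n_info > 0L)
    X[seq_len(n1), seq_len(n_info)] <- X[seq_len(n1), seq_len(n_info)] + delta
  y <- rep(c("responder", "nonresponder"), c(n1, n2))
  list(X = X, y = y)
}
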