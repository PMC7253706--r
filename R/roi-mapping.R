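# ROI discovery on the training set: voxelwise two-sample t-map, two-tailed
# cluster-extent thresholding, atlas-overlap annotation.

#' Default VBM analysis mask
#'
#' Voxels whose mean grey-matter value across the training maps exceeds a
#' threshold — the standard implicit-mask heuristic for modulated GM maps.
#'
#' @param maps List of [gm_map()] on one grid.
#' @param threshold Mean-GM cutoff, default 0.1.
#' @return A logical 3D array.
#' @export
gm_analysis_mask <- function(maps, threshold = 0.1) {
  d <- maps[[1L]]$grid_shape
  acc <- array(0, d)
  for (m in maps) acc <- acc + m$values
  acc / length(maps) > threshold
}

#' Voxelwise two-sample t-map between responders and non-responders
#'
#' At each in-mask voxel, the pooled-variance two-sample t statistic
#' comparing grey-matter volume between the two groups, with
#' df = n1 + n2 - 2 and no covariates. The contrast is responder minus
#' non-responder, so positive t means more grey matter in responders. Voxels
#' with zero pooled variance are dropped from the mask (count recorded).
#'
#' @param maps List of [gm_map()] (the training set).
#' @param labels Data frame from [label_response()] covering every map.
#' @param mask Logical 3D array; defaults to [gm_analysis_mask()].
#' @param p_threshold Voxel significance level stored for thresholding,
#'   default 0.05.
#' @param extent_threshold Cluster extent k in voxels, default 100.
#' @return A `t_stat_map` list: `t_values` (NA outside mask), `df`,
#'   `analysis_mask`, `p_threshold`, `extent_threshold`, `n_dropped`.
#' @export
voxelwise_t_map <- function(maps, labels, mask = gm_analysis_mask(maps),
                            p_threshold = 0.05, extent_threshold = 100L) {
  ids <- vapply(maps, function(m) m$subject_id, character(1L))
  lab <- labels$label[match(ids, labels$subject_id)]
  if (any(is.na(lab))) stop("labels missing for some maps")
  g1 <- lab == "responder"
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per class")
  d <- maps[[1L]]$grid_shape
  for (m in maps) if (!all(m$grid_shape == d)) stop("maps are not on one grid")

  X <- vapply(maps, function(m) m$values[mask], numeric(sum(mask)))
  m1 <- rowMeans(X[, g1, drop = FALSE])
  m2 <- rowMeans(X[, !g1, drop = FALSE])
  v1 <- rowSums((X[, g1, drop = FALSE] - m1)^2)
  v2 <- rowSums((X[, !g1, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (v1 + v2) / df
  tvals <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  degenerate <- sp2 <= 0
  tvals[degenerate] <- NA_real_

  keep <- mask
  keep[mask][degenerate] <- FALSE
  tv <- array(NA_real_, d)
  tv[mask] <- tvals
  structure(list(t_values = tv, df = df, analysis_mask = keep,
                 p_threshold = p_threshold,
                 extent_threshold = as.integer(extent_threshold),
                 n_dropped = sum(degenerate)),
            class = "t_stat_map")
}

# Neighbourhood offsets for 6-, 18- or 26-connectivity in 3D.
connectivity_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1L,
                 "18" = nz >= 1L & nz <= 2L,
                 "26" = nz >= 1L)
  off[keep, , drop = FALSE]
}

#' Label connected components of a 3D binary mask
#'
#' Breadth-first connected-component labelling under 6-, 18- or
#' 26-connectivity.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape; 0 = background, components are
#'   numbered 1..C in decreasing size order.
#' @export
label_components <- function(mask, connectivity = 18L) {
  d <- dim(mask)
  off <- connectivity_offsets(as.integer(connectivity))
  labs <- array(0L, d)
  todo <- which(mask)
  comp <- 0L
  for (start in todo) {
    if (labs[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    labs[start] <- comp
    while (length(queue) > 0L) {
      cur <- queue
      queue <- integer(0L)
      ijk <- index_to_vox(cur, d)
      for (r in seq_len(nrow(off))) {
        nb <- sweep(ijk, 2L, off[r, ], `+`)
        ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
        if (!any(ok)) next
        idx <- vox_to_index(nb[ok, , drop = FALSE], d)
        idx <- idx[mask[idx] & labs[idx] == 0L]
        if (length(idx) > 0L) {
          labs[idx] <- comp
          queue <- c(queue, idx)
        }
      }
      queue <- unique(queue)
    }
  }
  # renumber components by decreasing size (ties by first occurrence)
  if (comp > 0L) {
    sizes <- tabulate(labs[labs > 0L], nbins = comp)
    ord <- order(-sizes, seq_len(comp))
    remap <- integer(comp)
    remap[ord] <- seq_len(comp)
    labs[labs > 0L] <- remap[labs[labs > 0L]]
  }
  labs
}

#' Threshold a t-map into regions of interest
#'
#' Applies the two-tailed voxel threshold (|t| above the critical value of
#' the t distribution at `p_threshold` with the map's df), clusters
#' suprathreshold voxels separately for positive and negative excursions
#' (signs never merge), and discards clusters smaller than the extent
#' threshold k.
#'
#' @param tmap A `t_stat_map` from [voxelwise_t_map()].
#' @param connectivity Cluster connectivity: 6, 18 (default) or 26.
#' @return An `roi_set` list with one entry per surviving cluster:
#'   `roi_id`, `mask`, `size`, `sign` (+1 responder > non-responder, -1
#'   reverse), `peak_t`; ordered by decreasing size. An empty suprathreshold
#'   set yields an empty (valid) `roi_set`.
#' @export
threshold_clusters <- function(tmap, connectivity = 18L) {
  stopifnot(inherits(tmap, "t_stat_map"))
  tcrit <- stats::qt(1 - tmap$p_threshold / 2, df = tmap$df)
  rois <- list()
  for (sgn in c(1, -1)) {
    supra <- !is.na(tmap$t_values) & tmap$analysis_mask &
      (sgn * tmap$t_values > tcrit)
    if (!any(supra)) next
    labs <- label_components(supra, connectivity)
    for (cc in seq_len(max(labs))) {
      m <- labs == cc
      sz <- sum(m)
      if (sz < tmap$extent_threshold) next
      rois[[length(rois) + 1L]] <- list(
        mask = m, size = sz, sign = sgn,
        peak_t = sgn * max(sgn * tmap$t_values[m]))
    }
  }
  if (length(rois) > 0L) {
    rois <- rois[order(-vapply(rois, `[[`, integer(1L), "size"))]
    for (i in seq_along(rois)) {
      rois[[i]]$roi_id <- i
      rois[[i]]$atlas_label <- NA_character_
      rois[[i]]$overlap_fraction <- NA_real_
    }
  }
  structure(list(rois = rois, df = tmap$df, p_threshold = tmap$p_threshold,
                 extent_threshold = tmap$extent_threshold,
                 connectivity = as.integer(connectivity)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROI(s), p < %g two-tailed, extent >= %d, %d-connectivity\n",
              length(x$rois), x$p_threshold, x$extent_threshold, x$connectivity))
  invisible(x)
}

#' Annotate ROIs with atlas regions
#'
#' Labels each ROI with the atlas region covering strictly more than half of
#' its voxels; otherwise the ROI is `"unassigned"` and the three most
#' overlapping regions are recorded. The stored `overlap_fraction` is the
#' largest fraction of ROI voxels inside any single atlas region (background
#' does not count as a region).
#'
#' @param rois An `roi_set` from [threshold_clusters()].
#' @param atlas An [atlas_parcellation()] on the same grid.
#' @return The `roi_set` with `atlas_label`, `overlap_fraction` and (when
#'   unassigned) `top_regions` filled in.
#' @export
annotate_rois <- function(rois, atlas) {
  stopifnot(inherits(rois, "roi_set"), inherits(atlas, "atlas_parcellation"))
  for (i in seq_along(rois$rois)) {
    roi <- rois$rois[[i]]
    if (!all(dim(roi$mask) == atlas$grid_shape))
      stop("atlas grid does not match ROI grid")
    codes <- atlas$labels[roi$mask]
    codes <- codes[codes > 0L]
    if (length(codes) == 0L) {
      rois$rois[[i]]$atlas_label <- "unassigned"
      rois$rois[[i]]$overlap_fraction <- 0
      rois$rois[[i]]$top_regions <- character(0L)
      next
    }
    frac <- sort(table(codes) / roi$size, decreasing = TRUE)
    best_code <- names(frac)[1L]
    rois$rois[[i]]$overlap_fraction <- as.numeric(frac[1L])
    if (frac[1L] > 0.5) {
      rois$rois[[i]]$atlas_label <- unname(atlas$region_names[best_code])
    } else {
      rois$rois[[i]]$atlas_label <- "unassigned"
      top <- utils::head(names(frac), 3L)
      rois$rois[[i]]$top_regions <- unname(atlas$region_names[top])
    }
  }
  rois
}

#' Summarise an ROI set as a data frame
#'
#' @param rois An annotated `roi_set`.
#' @return Data frame with one row per ROI: id, size, sign, peak |t|, atlas
#'   label and overlap fraction.
#' @export
roi_summary <- function(rois) {
  if (length(rois$rois) == 0L)
    return(data.frame(roi_id = integer(0L), size = integer(0L),
                      sign = integer(0L), peak_t = numeric(0L),
                      atlas_label = character(0L),
                      overlap_fraction = numeric(0L)))
  do.call(rbind, lapply(rois$rois, function(r)
    data.frame(roi_id = r$roi_id, size = r$size, sign = r$sign,
               peak_t = r$peak_t,
               atlas_label = r$atlas_label %||% NA_character_,
               overlap_fraction = r$overlap_fraction,
               stringsAsFactors = FALSE)))
}

#' Write an ROI set as an integer label volume
#'
#' @param rois An `roi_set`.
#' @param grid_shape Grid dimensions (needed when the set is empty).
#' @param path Output NIfTI path.
#' @param affine Voxel-to-mm transform.
#' @return The path, invisibly.
#' @export
write_roi_volume <- function(rois, grid_shape, path, affine = diag(4)) {
  vol <- array(0L, grid_shape)
  for (r in rois$rois) vol[r$mask] <- r$roi_id
  write_volume(vol, path, affine, integer = TRUE)
}
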