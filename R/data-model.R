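#' Grey-matter map object
#'
#' A single subject's modulated grey-matter volume map: a 3D scalar field in a
#' common (DARTEL-normalised) space, together with the voxel-to-mm affine.
#' Voxel values are modulated GM volume fractions, so they are dimensionless,
#' finite and non-negative. All maps in a cohort must share one grid; the
#' pipeline performs no resampling.
#'
#' @param values Numeric 3D array of voxel values.
#' @param affine 4x4 voxel-to-mm transform (must be invertible).
#' @param subject_id Character identifier.
#' @return An object of class `gm_map` with fields `subject_id`, `values`,
#'   `affine` and `grid_shape`.
#' @export
gm_map <- function(values, affine = diag(4), subject_id = "subject") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  bad <- which(!is.finite(values))
  if (length(bad) > 0L) {
    ijk <- index_to_vox(bad[1L], dim(values))
    stop(sprintf("non-finite voxel at index (%d, %d, %d)%s",
                 ijk[1L], ijk[2L], ijk[3L],
                 if (length(bad) > 1L) sprintf(" (and %d more)", length(bad) - 1L) else ""))
  }
  if (any(values < 0))
    stop("grey-matter values must be non-negative")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be invertible")
  structure(list(subject_id = as.character(subject_id),
                 values = values,
                 affine = affine,
                 grid_shape = dim(values)),
            class = "gm_map")
}

#' @export
print.gm_map <- function(x, ...) {
  cat(sprintf("<gm_map> subject '%s', grid %s, range [%.4g, %.4g]\n",
              x$subject_id, paste(x$grid_shape, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Atlas parcellation object
#'
#' An integer-coded parcellation volume on the cohort grid: 0 is background,
#' codes 1..R are anatomical regions. Every nonzero code must have a name.
#'
#' @param labels Integer 3D array of region codes.
#' @param region_names Named character vector mapping code (as name) to region
#'   name, e.g. `c("1" = "Insula_L")`.
#' @return An object of class `atlas_parcellation`.
#' @export
atlas_parcellation <- function(labels, region_names) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  storage.mode(labels) <- "integer"
  codes <- sort(unique(labels[labels > 0L]))
  missing_names <- setdiff(as.character(codes), names(region_names))
  if (length(missing_names) > 0L)
    stop("region codes without names: ", paste(missing_names, collapse = ", "))
  structure(list(labels = labels,
                 region_names = region_names,
                 grid_shape = dim(labels)),
            class = "atlas_parcellation")
}

#' @export
print.atlas_parcellation <- function(x, ...) {
  cat(sprintf("<atlas_parcellation> %d regions on grid %s\n",
              length(x$region_names), paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' Performance report object
#'
#' Binary-classification performance: accuracy, sensitivity, specificity,
#' positive and negative predictive value (proportions in \[0, 1\], `NA` where
#' the defining ratio has a zero denominator), phi correlation coefficient in
#' \[-1, 1\], AUC, and the ROC curve as ordered (FPR, TPR) points from (0,0)
#' to (1,1). The stored AUC must equal the trapezoidal area of the ROC points.
#'
#' @param acc,sens,spec,ppv,npv Proportions in \[0, 1\] or `NA`.
#' @param auc Area under the ROC curve in \[0, 1\].
#' @param phi Phi coefficient in \[-1, 1\] or `NA`.
#' @param roc_points Data frame with numeric columns `fpr` and `tpr`.
#' @return An object of class `performance_report`.
#' @export
performance_report <- function(acc, sens, spec, ppv, npv, auc, phi, roc_points) {
  for (nm in c("acc", "sens", "spec", "ppv", "npv")) {
    v <- get(nm)
    if (!is.na(v)) stop_if_not_scalar_prob(v, nm)
  }
  stop_if_not_scalar_prob(auc, "auc")
  if (!is.na(phi) && (phi < -1 || phi > 1)) stop("'phi' must lie in [-1, 1]")
  if (!is.data.frame(roc_points) || !all(c("fpr", "tpr") %in% names(roc_points)))
    stop("'roc_points' must be a data frame with columns fpr, tpr")
  rp <- roc_points[order(roc_points$fpr, roc_points$tpr), , drop = FALSE]
  if (any(diff(rp$fpr) < -1e-12) || any(diff(rp$tpr) < -1e-12))
    stop("ROC points must be monotone nondecreasing")
  if (abs(rp$fpr[1L]) > 1e-12 || abs(rp$tpr[1L]) > 1e-12 ||
      abs(rp$fpr[nrow(rp)] - 1) > 1e-12 || abs(rp$tpr[nrow(rp)] - 1) > 1e-12)
    stop("ROC points must start at (0,0) and end at (1,1)")
  area <- trapezoid_auc(rp$fpr, rp$tpr)
  if (abs(area - auc) > 1e-8)
    stop(sprintf("stored auc (%.10f) does not match trapezoidal ROC area (%.10f)",
                 auc, area))
  structure(list(acc = acc, sens = sens, spec = spec, ppv = ppv, npv = npv,
                 auc = auc, phi = phi, roc_points = rp),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf(
    "<performance_report> ACC %s  SENS %s  SPEC %s  PPV %s  NPV %s  AUC %s  PHI %s\n",
    fmt(x$acc), fmt(x$sens), fmt(x$spec), fmt(x$ppv), fmt(x$npv),
    fmt(x$auc), fmt(x$phi)))
  invisible(x)
}

# Trapezoidal area under an ROC polyline.
trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
}

#' Validate a clinical cohort table
#'
#' Checks the per-record invariants of a clinical table: PANSS totals must
#' equal the sum of the three subscales within a rounding tolerance of 0.5 at
#' both time points, and scale scores must be positive. Missing values (the
#' ECT session count may be missing) are tolerated and excluded from checks.
#'
#' @param cohort Data frame of clinical records (see [read_cohort_table()]).
#' @param tol Rounding tolerance on the subscale sum, default 0.5.
#' @return The cohort, invisibly; emits a warning naming offending subjects.
#' @export
validate_cohort <- function(cohort, tol = 0.5) {
  for (when in c("baseline", "post")) {
    tot <- cohort[[paste0("panss_total_", when)]]
    sums <- cohort[[paste0("panss_positive_", when)]] +
      cohort[[paste0("panss_negative_", when)]] +
      cohort[[paste0("panss_general_", when)]]
    off <- which(!is.na(tot) & !is.na(sums) & abs(tot - sums) > tol)
    if (length(off) > 0L)
      warning(sprintf("PANSS total differs from subscale sum at %s for subject(s): %s",
                      when, paste(cohort$subject_id[off], collapse = ", ")),
              call. = FALSE)
  }
  scale_cols <- grep("^(panss_|cgi_)", names(cohort), value = TRUE)
  for (cl in scale_cols) {
    neg <- which(!is.na(cohort[[cl]]) & cohort[[cl]] <= 0)
    if (length(neg) > 0L)
      warning(sprintf("non-positive %s for subject(s): %s", cl,
                      paste(cohort$subject_id[neg], collapse = ", ")),
              call. = FALSE)
  }
  invisible(cohort)
}
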