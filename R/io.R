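# Readers and writers: NIfTI-1 volumes, clinical CSV tables, JSON reports.

# Write a bare 3D array as NIfTI-1 with the given affine, at full double
# precision so round trips are exact. Atlas volumes go out as int32.
write_volume <- function(values, path, affine = diag(4), integer = FALSE) {
  im <- RNifti::asNifti(if (integer) array(as.integer(values), dim(values)) else values)
  RNifti::pixdim(im) <- sqrt(colSums(affine[1:3, 1:3]^2))
  im <- RNifti::`sform<-`(im, structure(affine, code = 2L))
  im <- RNifti::`qform<-`(im, structure(affine, code = 2L))
  RNifti::writeNifti(im, path, datatype = if (integer) "int" else "double")
  invisible(path)
}

read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) == 4L && d[4L] == 1L) d <- d[1:3]
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(dim(im)), "D image: ", path)
  vals <- array(as.vector(im)[seq_len(prod(d))], d)
  list(values = vals, affine = unclass(RNifti::xform(im))[1:4, 1:4])
}

#' Read a grey-matter map from a NIfTI-1 file
#'
#' Reads a single-subject 3D modulated grey-matter volume map. The file must
#' contain exactly one 3D volume with finite, non-negative voxel values; a 4D
#' series or a map containing NaN/Inf voxels is rejected with a diagnostic
#' naming the offending voxel.
#'
#' @param path Path to a NIfTI file.
#' @param subject_id Identifier to attach; defaults to the file stem.
#' @return A [gm_map()] object.
#' @export
read_gm_map <- function(path, subject_id = NULL) {
  v <- read_volume(path)
  sid <- subject_id %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  gm_map(v$values, v$affine, sid)
}

#' Write a grey-matter map to NIfTI-1
#'
#' @param map A [gm_map()] object.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_gm_map <- function(map, path) {
  stopifnot(inherits(map, "gm_map"))
  write_volume(map$values, path, map$affine)
}

#' Read an atlas parcellation from NIfTI-1 plus a region-name table
#'
#' @param path Path to the integer-coded NIfTI label volume.
#' @param names_path Path to a two-column CSV (`code,name`); if `NULL`, codes
#'   are named `region_<code>`.
#' @return An [atlas_parcellation()] object.
#' @export
read_atlas <- function(path, names_path = NULL) {
  v <- read_volume(path)
  labs <- array(as.integer(round(v$values)), dim(v$values))
  if (!is.null(names_path)) {
    tab <- utils::read.csv(names_path, stringsAsFactors = FALSE)
    region_names <- stats::setNames(as.character(tab$name), as.character(tab$code))
  } else {
    codes <- sort(unique(labs[labs > 0L]))
    region_names <- stats::setNames(paste0("region_", codes), as.character(codes))
  }
  atlas_parcellation(labs, region_names)
}

#' Write an atlas parcellation
#'
#' Writes the label volume as int32 NIfTI and the region names as CSV.
#'
#' @param atlas An [atlas_parcellation()] object.
#' @param path Output NIfTI path.
#' @param names_path Output CSV path; default replaces the extension.
#' @param affine Voxel-to-mm transform for the label volume.
#' @return The NIfTI path, invisibly.
#' @export
write_atlas <- function(atlas, path, names_path = NULL,
                        affine = diag(4)) {
  stopifnot(inherits(atlas, "atlas_parcellation"))
  write_volume(atlas$labels, path, affine, integer = TRUE)
  names_path <- names_path %||% sub("\\.nii(\\.gz)?$", "_regions.csv", path)
  utils::write.csv(
    data.frame(code = names(atlas$region_names),
               name = unname(atlas$region_names)),
    names_path, row.names = FALSE)
  invisible(path)
}

#' Read a clinical cohort table
#'
#' Reads a CSV of per-subject clinical records (demographics, CGI, PANSS
#' subscales and totals at baseline and after ECT, olanzapine-equivalent
#' antipsychotic dose, ECT session count). Each row is checked against the
#' PANSS-sum invariant (total = positive + negative + general within 0.5);
#' violations produce a warning listing the subject ids.
#'
#' @param path Path to a CSV file with a header.
#' @return A data frame with one row per subject.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(cohort) == 0L)
    stop("clinical table is empty: ", path)
  if (!"subject_id" %in% names(cohort))
    stop("clinical table must have a 'subject_id' column")
  cohort$subject_id <- as.character(cohort$subject_id)
  validate_cohort(cohort)
  cohort
}

#' Write a clinical cohort table
#'
#' @param cohort Data frame of clinical records.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write a performance report to JSON
#'
#' Serialises a [performance_report()] (plus optional metadata such as the
#' seed and configuration hash) at full double precision, so re-reading the
#' file reproduces every number bit-exactly.
#'
#' @param report A [performance_report()] object.
#' @param path Output JSON path.
#' @param metadata Optional named list stored alongside the metrics.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, metadata = list()) {
  stopifnot(inherits(report, "performance_report"))
  payload <- list(
    metrics = report[c("acc", "sens", "spec", "ppv", "npv", "auc", "phi")],
    roc_points = report$roc_points,
    metadata = metadata)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a performance report written by [write_report()]
#'
#' @param path JSON path.
#' @return A list with elements `report` (a [performance_report()]) and
#'   `metadata`.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- lapply(payload$metrics, function(v) if (is.null(v)) NA_real_ else v)
  rp <- as.data.frame(payload$roc_points)
  list(report = performance_report(m$acc, m$sens, m$spec, m$ppv, m$npv,
                                   m$auc, m$phi, rp),
       metadata = payload$metadata)
}
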