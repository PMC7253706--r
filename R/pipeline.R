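# End-to-end orchestration: simulate -> define ROIs -> extract features ->
# LOOCV (LRM and SVM) -> distill -> fuse -> report, as one reproducible run.

#' Pipeline configuration
#'
#' Collects every stage parameter in one validated object. A single master
#' seed deterministically derives all stage seeds, so the whole run — and any
#' stage rerun in isolation — is reproducible.
#'
#' @param synthesis A [synthesis_config()] describing the synthetic cohort.
#' @param train_counts Per-class training counts for [split_cohort()].
#' @param p_threshold Voxel significance level, default 0.05.
#' @param extent_threshold Cluster extent k in voxels, default 100.
#' @param connectivity Cluster connectivity (6/18/26), default 18.
#' @param n_bins Histogram bins for feature extraction, default 64.
#' @param alpha In-fold univariate filter level, default 0.05.
#' @param lambda_selection LASSO lambda strategy (`"min"`, `"1se"`, or fixed).
#' @param inner_folds Inner CV folds, default 5.
#' @param svm_cost Linear-SVM cost, default 1.
#' @param freq_threshold Selection-frequency cutoff, default 0.5.
#' @param k_fixed Fixed radiomic model size, default 3.
#' @param decision_threshold Probability threshold, default 0.5.
#' @param vif_limit Fusion multicollinearity limit, default 4.
#' @param clinical_covariates Clinical columns offered to the fusion model.
#' @param exclude_ids Subject ids excluded before the split.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthesis = synthesis_config(),
                            train_counts = c(responder = 22L,
                                             nonresponder = 22L),
                            p_threshold = 0.05, extent_threshold = 100L,
                            connectivity = 18L, n_bins = 64L, alpha = 0.05,
                            lambda_selection = "min", inner_folds = 5L,
                            svm_cost = 1, freq_threshold = 0.5, k_fixed = 3L,
                            decision_threshold = 0.5, vif_limit = 4,
                            clinical_covariates = c("panss_negative_baseline",
                                                    "dose_ddd"),
                            exclude_ids = character(0L),
                            seed = 1L) {
  stop_if_not_scalar_prob(p_threshold, "p_threshold")
  stop_if_not_scalar_prob(alpha, "alpha")
  stop_if_not_scalar_prob(freq_threshold, "freq_threshold")
  stop_if_not_scalar_prob(decision_threshold, "decision_threshold")
  stopifnot(extent_threshold >= 1L, connectivity %in% c(6L, 18L, 26L),
            n_bins >= 2L, inner_folds >= 2L, svm_cost > 0, k_fixed >= 1L,
            vif_limit > 1)
  structure(list(synthesis = synthesis, train_counts = train_counts,
                 p_threshold = p_threshold,
                 extent_threshold = as.integer(extent_threshold),
                 connectivity = as.integer(connectivity),
                 n_bins = as.integer(n_bins), alpha = alpha,
                 lambda_selection = lambda_selection,
                 inner_folds = as.integer(inner_folds), svm_cost = svm_cost,
                 freq_threshold = freq_threshold, k_fixed = as.integer(k_fixed),
                 decision_threshold = decision_threshold,
                 vif_limit = vif_limit,
                 clinical_covariates = clinical_covariates,
                 exclude_ids = exclude_ids, seed = as.integer(seed)),
            class = "pipeline_config")
}

# JSON-serialisable view of a config (for hashing and provenance).
config_as_list <- function(config) {
  out <- unclass(config)
  out$synthesis <- unclass(out$synthesis)
  out
}

#' Run the full radiomics pipeline on a synthetic cohort
#'
#' Executes, in order: cohort synthesis, train/validation split, training-set
#' t-map and ROI definition, atlas annotation, feature extraction and
#' training-only standardization, LOOCV with the LASSO logistic classifier
#' and with the linear SVM, selection-frequency distillation into the fixed
#' radiomic model, and the clinical-fusion model. When `out_dir` is given,
#' every artifact (t-map and ROI volumes, feature CSVs, per-fold JSON,
#' reports with seed and config hash) is written there.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; created if missing.
#' @param split Optional pre-computed cohort split (list with `train_ids`,
#'   `validation_ids`), used by sensitivity reruns to keep set membership
#'   fixed; `NULL` draws the split from the config seed.
#' @return A `pipeline_run` list with all intermediate and final objects.
#' @export
run_pipeline <- function(config, out_dir = NULL, split = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  chash <- config_hash(config_as_list(config))

  # stage 1: synthesis
  cohort <- synthesize_cohort(config$synthesis)
  if (length(config$exclude_ids) > 0L) {
    missing_ids <- setdiff(config$exclude_ids, cohort$labels$subject_id)
    if (length(missing_ids) > 0L)
      stop("exclude_ids not in cohort: ", paste(missing_ids, collapse = ", "))
    keep <- !(cohort$labels$subject_id %in% config$exclude_ids)
    cohort$maps <- cohort$maps[keep]
    cohort$clinical <- cohort$clinical[keep, , drop = FALSE]
    cohort$labels <- cohort$labels[keep, , drop = FALSE]
    if (length(unique(cohort$labels$label)) < 2L)
      stop("exclusion emptied a class")
  }

  # stage 2: split (cap the per-class request at what exclusion left over)
  if (is.null(split)) {
    sizes <- table(cohort$labels$label)
    tc <- config$train_counts
    for (cl in names(tc)) tc[cl] <- min(tc[cl], max(sizes[[cl]] - 1L, 1L))
    split <- split_cohort(cohort$labels, train_counts = tc,
                          seed = derive_seed(config$seed, "split"))
  } else {
    split <- list(
      train_ids = intersect(split$train_ids, cohort$labels$subject_id),
      validation_ids = intersect(split$validation_ids,
                                 cohort$labels$subject_id),
      seed = split$seed %||% NA_integer_)
  }
  ids <- vapply(cohort$maps, function(m) m$subject_id, character(1L))
  train_maps <- cohort$maps[ids %in% split$train_ids]
  val_maps <- cohort$maps[ids %in% split$validation_ids]

  # stage 3: ROI definition on the training set only
  tmap <- voxelwise_t_map(train_maps, cohort$labels,
                          p_threshold = config$p_threshold,
                          extent_threshold = config$extent_threshold)
  rois <- threshold_clusters(tmap, config$connectivity)
  rois <- annotate_rois(rois, cohort$atlas)
  if (length(rois$rois) == 0L) {
    res <- structure(list(config = config, config_hash = chash,
                          cohort = cohort, split = split, tmap = tmap,
                          rois = rois, n_features = 0L,
                          status = "no ROIs survived thresholding"),
                     class = "pipeline_run")
    if (!is.null(out_dir)) persist_run(res, out_dir)
    return(res)
  }

  # stage 4: features + leakage-free standardization
  X_train_raw <- feature_matrix(train_maps, rois, config$n_bins)
  X_val_raw <- feature_matrix(val_maps, rois, config$n_bins)
  std <- fit_standardizer(X_train_raw)
  X_train <- apply_standardizer(X_train_raw, std)
  X_val <- apply_standardizer(X_val_raw, std)
  lab_of <- function(id_set)
    cohort$labels$label[match(id_set, cohort$labels$subject_id)]
  y_train <- lab_of(rownames(X_train))
  y_val <- lab_of(rownames(X_val))

  # stage 5: LOOCV, LRM then SVM replication
  cv_lrm <- run_loocv(X_train, y_train, X_val, y_val, "lrm",
                      alpha = config$alpha,
                      lambda_selection = config$lambda_selection,
                      inner_folds = config$inner_folds,
                      decision_threshold = config$decision_threshold,
                      seed = derive_seed(config$seed, "loocv"))
  cv_svm <- run_loocv(X_train, y_train, X_val, y_val, "svm",
                      alpha = config$alpha,
                      lambda_selection = config$lambda_selection,
                      inner_folds = config$inner_folds,
                      svm_cost = config$svm_cost,
                      seed = derive_seed(config$seed, "loocv"))
  delong_lrm <- delong_unpaired(
    vapply(cv_lrm$fold_results, `[[`, numeric(1L), "heldout_score"),
    y_train,
    rowMeans(vapply(cv_lrm$fold_results, `[[`, numeric(nrow(X_val)),
                    "validation_scores")),
    y_val)
  delong_svm <- delong_unpaired(
    vapply(cv_svm$fold_results, `[[`, numeric(1L), "heldout_score"),
    y_train,
    rowMeans(vapply(cv_svm$fold_results, `[[`, numeric(nrow(X_val)),
                    "validation_scores")),
    y_val)

  # stage 6: distillation
  ranking <- selection_frequency(cv_lrm)
  fixed_features <- select_fixed_features(ranking, config$freq_threshold,
                                          config$k_fixed)
  fixed_model <- if (length(fixed_features) > 0L)
    fit_fixed_lrm(X_train, y_train, X_val, y_val, fixed_features,
                  config$decision_threshold) else NULL

  # stage 7: clinical fusion
  fusion <- NULL
  if (!is.null(fixed_model) && length(config$clinical_covariates) > 0L) {
    clin <- cohort$clinical[match(rownames(X_train),
                                  cohort$clinical$subject_id),
                            config$clinical_covariates, drop = FALSE]
    fusion <- build_fusion_model(X_train, clin, y_train, fixed_features,
                                 vif_limit = config$vif_limit)
  }

  res <- structure(list(config = config, config_hash = chash,
                        cohort = cohort, split = split,
                        tmap = tmap, rois = rois,
                        roi_table = roi_summary(rois),
                        standardizer = std,
                        X_train = X_train, X_val = X_val,
                        y_train = y_train, y_val = y_val,
                        n_features = ncol(X_train_raw),
                        cv_lrm = cv_lrm, cv_svm = cv_svm,
                        delong_lrm = delong_lrm, delong_svm = delong_svm,
                        ranking = ranking, fixed_features = fixed_features,
                        fixed_model = fixed_model, fusion = fusion,
                        status = "complete"),
                   class = "pipeline_run")
  if (!is.null(out_dir)) persist_run(res, out_dir)
  res
}

#' Rerun the pipeline excluding subjects, with a comparison summary
#'
#' Sensitivity reanalysis: reruns the identical pipeline on the cohort minus
#' `excluded_ids` (e.g. dropping an unmedicated patient) and summarises the
#' change — delta accuracy, delta AUC, and an unpaired DeLong test between
#' the original and the reduced validation ROC curves.
#'
#' @param config A [pipeline_config()].
#' @param excluded_ids Subject ids to drop.
#' @param original An existing `pipeline_run` of `config`, or `NULL` to
#'   compute it.
#' @param out_dir Optional output directory for the reduced run.
#' @return A list with `original`, `reduced` and `comparison` (data frame).
#' @export
rerun_excluding <- function(config, excluded_ids, original = NULL,
                            out_dir = NULL) {
  if (is.null(original)) original <- run_pipeline(config)
  cfg2 <- config
  cfg2$exclude_ids <- unique(c(config$exclude_ids, excluded_ids))
  # keep the original set membership: the rerun drops subjects, it does not
  # redraw the split
  reduced <- run_pipeline(cfg2, out_dir, split = original$split)
  val_scores <- function(run)
    rowMeans(vapply(run$cv_lrm$fold_results, `[[`,
                    numeric(length(run$y_val)), "validation_scores"))
  dl <- delong_unpaired(val_scores(original), original$y_val,
                        val_scores(reduced), reduced$y_val)
  comparison <- data.frame(
    delta_training_acc = reduced$cv_lrm$training_report$acc -
      original$cv_lrm$training_report$acc,
    delta_validation_acc = reduced$cv_lrm$validation_report$acc -
      original$cv_lrm$validation_report$acc,
    delta_training_auc = reduced$cv_lrm$training_report$auc -
      original$cv_lrm$training_report$auc,
    delta_validation_auc = reduced$cv_lrm$validation_report$auc -
      original$cv_lrm$validation_report$auc,
    delong_p_validation = dl$p)
  list(original = original, reduced = reduced, comparison = comparison)
}

# Write every artifact of a run to a directory.
persist_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = run$config$seed, config_hash = run$config_hash,
               status = run$status)
  jsonlite::write_json(c(meta, list(config = config_as_list(run$config))),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  write_cohort_table(run$cohort$clinical, file.path(out_dir, "clinical.csv"))
  utils::write.csv(run$cohort$labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  write_atlas(run$cohort$atlas, file.path(out_dir, "atlas.nii.gz"))
  if (!is.null(run$tmap)) {
    tv <- run$tmap$t_values
    tv[is.na(tv)] <- 0
    write_volume(tv, file.path(out_dir, "tmap.nii.gz"))
  }
  if (!is.null(run$rois))
    write_roi_volume(run$rois, run$config$synthesis$grid_shape,
                     file.path(out_dir, "rois.nii.gz"))
  if (!is.null(run$roi_table))
    utils::write.csv(run$roi_table, file.path(out_dir, "rois.csv"),
                     row.names = FALSE)
  if (run$status != "complete") {
    jsonlite::write_json(meta, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out_dir))
  }
  utils::write.csv(run$X_train, file.path(out_dir, "features_train.csv"))
  utils::write.csv(run$X_val, file.path(out_dir, "features_validation.csv"))
  jsonlite::write_json(
    lapply(run$cv_lrm$fold_results, function(fr)
      fr[c("fold_id", "filtered_features", "selected_features", "lambda",
           "coefficients", "heldout_score", "validation_scores")]),
    file.path(out_dir, "folds_lrm.json"), auto_unbox = TRUE, digits = I(17))
  write_report(run$cv_lrm$training_report,
               file.path(out_dir, "report_lrm_training.json"), meta)
  write_report(run$cv_lrm$validation_report,
               file.path(out_dir, "report_lrm_validation.json"), meta)
  write_report(run$cv_svm$training_report,
               file.path(out_dir, "report_svm_training.json"), meta)
  write_report(run$cv_svm$validation_report,
               file.path(out_dir, "report_svm_validation.json"), meta)
  utils::write.csv(run$ranking, file.path(out_dir, "selection_frequency.csv"),
                   row.names = FALSE)
  summary_json <- list(
    seed = run$config$seed, config_hash = run$config_hash,
    n_rois = length(run$rois$rois), n_features = run$n_features,
    lrm = list(training_acc = run$cv_lrm$training_report$acc,
               training_auc = run$cv_lrm$training_report$auc,
               validation_acc = run$cv_lrm$validation_report$acc,
               validation_auc = run$cv_lrm$validation_report$auc,
               delong_p = run$delong_lrm$p),
    svm = list(training_acc = run$cv_svm$training_report$acc,
               training_auc = run$cv_svm$training_report$auc,
               validation_acc = run$cv_svm$validation_report$acc,
               validation_auc = run$cv_svm$validation_report$auc,
               delong_p = run$delong_svm$p),
    fixed_features = run$fixed_features,
    fusion_retained_clinical = if (!is.null(run$fusion))
      run$fusion$retained_clinical else character(0L))
  jsonlite::write_json(summary_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> status: %s, seed %d, config %s\n",
              x$status, x$config$seed, x$config_hash))
  if (x$status == "complete") {
    cat(sprintf("  %d ROIs -> %d features; train n=%d, validation n=%d\n",
                length(x$rois$rois), x$n_features,
                length(x$y_train), length(x$y_val)))
    cat("  LRM "); print(x$cv_lrm$training_report)
    cat("  SVM "); print(x$cv_svm$training_report)
  }
  invisible(x)
}

#' Baseline group-comparison table for a synthetic cohort
#'
#' Descriptive side table in the style of a demographics table: per-variable
#' responder / non-responder means (SD) with Welch t-test p-values, and a
#' chi-square test for the sex ratio.
#'
#' @param clinical Clinical data frame with a `group` column.
#' @return Data frame with one row per compared variable.
#' @export
demographics_table <- function(clinical) {
  num_vars <- c("age", "education", "duration_illness", "cgi_baseline",
                "cgi_post", "panss_positive_baseline",
                "panss_negative_baseline", "panss_general_baseline",
                "panss_total_baseline", "panss_total_post", "dose_ddd")
  num_vars <- intersect(num_vars, names(clinical))
  g <- clinical$group == "responder"
  rows <- lapply(num_vars, function(v) {
    x <- clinical[[v]]
    data.frame(variable = v,
               responder = sprintf("%.1f (%.1f)", mean(x[g], na.rm = TRUE),
                                   stats::sd(x[g], na.rm = TRUE)),
               nonresponder = sprintf("%.1f (%.1f)", mean(x[!g], na.rm = TRUE),
                                      stats::sd(x[!g], na.rm = TRUE)),
               p = stats::t.test(x[g], x[!g])$p.value,
               stringsAsFactors = FALSE)
  })
  if ("sex" %in% names(clinical)) {
    tab <- table(clinical$group, clinical$sex)
    p_sex <- if (all(dim(tab) == c(2L, 2L)))
      suppressWarnings(stats::chisq.test(tab)$p.value) else NA_real_
    rows <- c(rows, list(data.frame(
      variable = "sex (male proportion)",
      responder = sprintf("%.2f", mean(clinical$sex[g])),
      nonresponder = sprintf("%.2f", mean(clinical$sex[!g])),
      p = p_sex, stringsAsFactors = FALSE)))
  }
  do.call(rbind, rows)
}
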