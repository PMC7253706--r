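# Distilling the LOOCV ensemble: selection-frequency ranking, the fixed
# three-feature radiomic logistic model, and the clinical-fusion model with
# VIF and coefficient-significance screening.

#' Selection frequency of features across LOOCV partitions
#'
#' Counts, for every feature, the number of LOOCV folds in which its LASSO
#' coefficient was nonzero; frequency = count / n_partitions. The ranking is
#' sorted by frequency, ties broken by mean |coefficient| across selecting
#' folds, then by name.
#'
#' @param cv_run A `cv_run` from [run_loocv()].
#' @return Data frame with `feature`, `count`, `frequency`, `mean_abs_coef`,
#'   sorted as above.
#' @export
selection_frequency <- function(cv_run) {
  stopifnot(inherits(cv_run, "cv_run"))
  n_part <- length(cv_run$fold_results)
  sel <- lapply(cv_run$fold_results, `[[`, "selected_features")
  coefs <- lapply(cv_run$fold_results, `[[`, "coefficients")
  feats <- sort(unique(unlist(sel)))
  if (length(feats) == 0L)
    return(data.frame(feature = character(0L), count = integer(0L),
                      frequency = numeric(0L), mean_abs_coef = numeric(0L)))
  count <- vapply(feats, function(f)
    sum(vapply(sel, function(s) f %in% s, logical(1L))), integer(1L))
  mean_abs <- vapply(feats, function(f) {
    v <- unlist(lapply(coefs, function(cf) abs(cf[f])))
    mean(v, na.rm = TRUE)
  }, numeric(1L))
  rk <- data.frame(feature = feats, count = count,
                   frequency = count / n_part, mean_abs_coef = mean_abs,
                   stringsAsFactors = FALSE)
  rk[order(-rk$frequency, -rk$mean_abs_coef, rk$feature), , drop = FALSE]
}

#' Select the fixed radiomic feature set from a frequency ranking
#'
#' Keeps features selected in strictly more than `freq_threshold` of the
#' partitions, then truncates to the top `k` (default 3, the size of the
#' final radiomic model). If fewer than `k` pass, all passers are returned
#' with a warning; if none pass, an empty set is returned with a warning.
#'
#' @param ranking Data frame from [selection_frequency()].
#' @param freq_threshold Strict frequency cutoff, default 0.5.
#' @param k Maximum number of fixed features, default 3.
#' @return Character vector of at most `k` feature names.
#' @export
select_fixed_features <- function(ranking, freq_threshold = 0.5, k = 3L) {
  passers <- ranking$feature[ranking$frequency > freq_threshold]
  if (length(passers) == 0L) {
    warning("no feature exceeds the selection-frequency threshold",
            call. = FALSE)
    return(character(0L))
  }
  if (length(passers) < k)
    warning(sprintf("only %d feature(s) exceed the frequency threshold (k = %d)",
                    length(passers), k), call. = FALSE)
  utils::head(passers, k)
}

#' Fit the fixed-feature radiomic logistic model
#'
#' Unpenalised multivariate logistic regression on the full training set,
#' restricted to the fixed radiomic features, validated on the validation
#' set, with an unpaired DeLong comparison of the two ROC curves attached.
#' Perfect separation is flagged rather than silently accepted.
#'
#' @param X_train,y_train Standardized training matrix and labels.
#' @param X_val,y_val Standardized validation matrix and labels.
#' @param features Fixed feature names (columns of both matrices).
#' @param decision_threshold Probability threshold, default 0.5.
#' @return A `fixed_lrm` list: `fit` (the glm), `coefficients` (with Wald z
#'   and p), `training_report`, `validation_report`, `delong`,
#'   `separation_warning`.
#' @export
fit_fixed_lrm <- function(X_train, y_train, X_val, y_val, features,
                          decision_threshold = 0.5) {
  stopifnot(all(features %in% colnames(X_train)),
            all(features %in% colnames(X_val)))
  g <- as_positive(y_train)
  dat <- data.frame(y = g, X_train[, features, drop = FALSE],
                    check.names = FALSE)
  sep_warn <- FALSE
  withCallingHandlers(
    fit <- stats::glm(y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- summary(fit)$coefficients
  train_scores <- stats::predict(fit, type = "response")
  val_scores <- stats::predict(
    fit, newdata = data.frame(X_val[, features, drop = FALSE],
                              check.names = FALSE),
    type = "response")
  training_report <- report_from_scores(train_scores, g, decision_threshold)
  validation_report <- report_from_scores(val_scores, as_positive(y_val),
                                          decision_threshold)
  dl <- delong_unpaired(train_scores, g, val_scores, as_positive(y_val))
  structure(list(fit = fit, coefficients = cf, features = features,
                 training_report = training_report,
                 validation_report = validation_report,
                 delong = dl, separation_warning = sep_warn),
            class = "fixed_lrm")
}

#' Variance inflation factors of a covariate design
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j comes from regressing covariate j on
#' all the others (with intercept). Exact collinearity yields an infinite
#' VIF.
#'
#' @param design Numeric matrix with >= 2 named covariate columns and more
#'   rows than covariates.
#' @return Named numeric vector of VIFs.
#' @export
compute_vif <- function(design) {
  if (ncol(design) < 2L) stop("need at least 2 covariates")
  if (nrow(design) <= ncol(design)) stop("need more rows than covariates")
  vapply(seq_len(ncol(design)), function(j) {
    fit <- stats::lm.fit(cbind(1, design[, -j, drop = FALSE]), design[, j])
    y <- design[, j]
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    if (sst <= 0) return(Inf)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L), USE.NAMES = FALSE) |> stats::setNames(colnames(design))
}

#' Build the clinical-fusion logistic model with covariate screening
#'
#' Combines the fixed radiomic features with clinical covariates (e.g. the
#' baseline PANSS negative score and antipsychotic dose) and screens the
#' clinical covariates in two deterministic passes: (1) while any covariate
#' in the design has VIF >= `vif_limit`, drop the clinical covariate with
#' the largest VIF; (2) refit and drop clinical covariates whose Wald
#' coefficient test has p >= `sig_level`, one at a time, largest p first.
#' Radiomic features are never dropped. If every clinical covariate is
#' removed the result is the pure radiomic model.
#'
#' @param X_train Standardized training matrix holding the radiomic features.
#' @param clinical Data frame / matrix of clinical covariates (training rows,
#'   named columns).
#' @param y_train Binary labels.
#' @param radiomic_features Fixed radiomic feature names.
#' @param vif_limit Multicollinearity limit, default 4 (removal at VIF >= 4).
#' @param sig_level Coefficient-significance level, default 0.05.
#' @return A `fusion_model` list: `fit`, `retained_clinical`, `vif` (final
#'   design VIFs), `coefficients`, `trace` (data frame logging every
#'   screening step).
#' @export
build_fusion_model <- function(X_train, clinical, y_train, radiomic_features,
                               vif_limit = 4, sig_level = 0.05) {
  g <- as_positive(y_train)
  clinical <- as.matrix(clinical)
  if (nrow(clinical) != nrow(X_train))
    stop("clinical covariates must cover all training subjects")
  if (any(is.na(clinical)))
    stop("clinical covariates contain missing values; exclude those columns or subjects")
  clin_names <- colnames(clinical)
  trace <- data.frame(step = character(0L), covariate = character(0L),
                      value = numeric(0L), stringsAsFactors = FALSE)

  design <- function(clin) {
    cbind(X_train[, radiomic_features, drop = FALSE],
          clinical[, clin, drop = FALSE])
  }

  # pass 1: multicollinearity
  retained <- clin_names
  repeat {
    D <- design(retained)
    if (ncol(D) < 2L) break
    vifs <- compute_vif(D)
    offenders <- vifs[names(vifs) %in% retained & vifs >= vif_limit]
    if (max(vifs) < vif_limit || length(offenders) == 0L) break
    drop <- names(offenders)[which.max(offenders)]
    trace <- rbind(trace, data.frame(step = "vif", covariate = drop,
                                     value = unname(offenders[drop])))
    retained <- setdiff(retained, drop)
    if (length(retained) == 0L) break
  }

  # pass 2: coefficient significance (Wald tests), clinical covariates only
  repeat {
    if (length(retained) == 0L) break
    D <- design(retained)
    dat <- data.frame(y = g, D, check.names = FALSE)
    fit <- suppressWarnings(stats::glm(y ~ ., data = dat,
                                       family = stats::binomial()))
    cf <- summary(fit)$coefficients
    rn <- rownames(cf)
    clin_rows <- rn[gsub("`", "", rn) %in% retained]
    pv <- cf[clin_rows, "Pr(>|z|)"]
    names(pv) <- gsub("`", "", clin_rows)
    bad <- pv[pv >= sig_level]
    if (length(bad) == 0L) break
    drop <- names(bad)[which.max(bad)]
    trace <- rbind(trace, data.frame(step = "significance", covariate = drop,
                                     value = unname(bad[drop])))
    retained <- setdiff(retained, drop)
  }

  D <- design(retained)
  dat <- data.frame(y = g, D, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = dat,
                                     family = stats::binomial()))
  final_vif <- if (ncol(D) >= 2L) compute_vif(D) else
    stats::setNames(rep(NA_real_, ncol(D)), colnames(D))
  structure(list(fit = fit, retained_clinical = retained,
                 radiomic_features = radiomic_features,
                 vif = final_vif, coefficients = summary(fit)$coefficients,
                 trace = trace, vif_limit = vif_limit,
                 sig_level = sig_level),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %d radiomic feature(s) + clinical {%s}\n",
              length(x$radiomic_features),
              paste(x$retained_clinical, collapse = ", ")))
  if (nrow(x$trace) > 0L) {
    cat("screening trace:\n")
    print(x$trace)
  }
  invisible(x)
}
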