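# Leave-one-out cross-validated classification: in-fold univariate filtering,
# LASSO-penalised logistic regression, linear-SVM replication, and the
# training/validation performance reports.

#' Univariate two-sample t-test feature filter
#'
#' Retains the features whose pooled-variance two-sample t-test between
#' responders and non-responders — computed only on the rows passed in —
#' has p < `alpha` (uncorrected). Zero-variance features are excluded with a
#' warning.
#'
#' @param X Numeric feature matrix (rows = subjects).
#' @param y Binary labels for the rows.
#' @param alpha Significance level, default 0.05.
#' @return Character vector of retained feature names.
#' @export
univariate_filter <- function(X, y, alpha = 0.05) {
  g <- as_positive(y)
  n1 <- sum(g); n2 <- sum(!g)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per class")
  m1 <- colMeans(X[g, , drop = FALSE])
  m2 <- colMeans(X[!g, , drop = FALSE])
  ss1 <- colSums(sweep(X[g, , drop = FALSE], 2L, m1)^2)
  ss2 <- colSums(sweep(X[!g, , drop = FALSE], 2L, m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  degenerate <- sp2 <= 0
  if (any(degenerate))
    warning(sprintf("excluding %d zero-variance feature(s) from the filter",
                    sum(degenerate)), call. = FALSE)
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  pval <- 2 * stats::pt(-abs(tval), df = df)
  colnames(X)[!degenerate & pval < alpha]
}

#' Fit a LASSO-penalised logistic regression
#'
#' Minimises the binomial negative log-likelihood plus an L1 penalty on the
#' coefficients (intercept unpenalised). The penalty lambda is chosen by
#' inner k-fold cross-validation minimising binomial deviance
#' (`lambda_selection = "min"`, the default) or by the one-standard-error
#' rule (`"1se"`); a fixed numeric lambda is also accepted. Features with
#' nonzero coefficients are the selected set. Inputs are assumed already
#' standardized; no internal rescaling is applied.
#'
#' @param X Standardized numeric feature matrix.
#' @param y Binary labels.
#' @param lambda_selection `"min"`, `"1se"`, or a fixed numeric lambda.
#' @param inner_folds Inner CV fold count, default 5.
#' @param seed Seed for the inner fold assignment.
#' @return A `lasso_lr` list: `beta` (named, possibly empty), `intercept`,
#'   `lambda`, `selected` (names of nonzero-coefficient features),
#'   `features` (the columns the model expects), `intercept_only` flag.
#' @export
fit_lasso_lr <- function(X, y, lambda_selection = "min", inner_folds = 5L,
                         seed = 1L) {
  g <- as_positive(y)
  if (length(unique(g)) < 2L) stop("both classes must be present")
  features <- colnames(X)
  if (ncol(X) > 0L && is.null(features)) stop("X must have column names")

  if (ncol(X) == 0L) {
    prev <- mean(g)
    return(structure(list(beta = stats::setNames(numeric(0L), character(0L)),
                          intercept = stats::qlogis(prev), lambda = NA_real_,
                          selected = character(0L), features = character(0L),
                          intercept_only = TRUE),
                     class = "lasso_lr"))
  }
  # glmnet requires >= 2 columns; a zero dummy column can never be selected.
  Xfit <- X
  dummy <- ncol(Xfit) == 1L
  if (dummy) Xfit <- cbind(Xfit, `.dummy` = 0)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "inner_cv"))

  if (is.numeric(lambda_selection)) {
    lambda <- lambda_selection
  } else {
    nf <- min(inner_folds, sum(g), sum(!g))
    foldid <- integer(length(g))
    foldid[g] <- sample(rep_len(seq_len(nf), sum(g)))
    foldid[!g] <- sample(rep_len(seq_len(nf), sum(!g)))
    # small LOOCV remainders trip glmnet's per-fold class-size advisory;
    # that is inherent to the design, so keep the log quiet
    withCallingHandlers(
      cvfit <- glmnet::cv.glmnet(Xfit, g, family = "binomial", alpha = 1,
                                 standardize = FALSE, foldid = foldid,
                                 type.measure = "deviance"),
      warning = function(w) {
        if (grepl("fewer than 8|grouped=FALSE|Convergence",
                  conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    lambda <- if (identical(lambda_selection, "1se")) cvfit$lambda.1se
              else cvfit$lambda.min
  }
  # warm-start path ending at the target lambda: much more reliable than a
  # single-lambda fit, especially near separation
  path <- lambda * c(16, 8, 4, 2, 1.5, 1.2, 1)
  withCallingHandlers(
    fit <- glmnet::glmnet(Xfit, g, family = "binomial", alpha = 1,
                          standardize = FALSE, lambda = path,
                          thresh = 1e-12, maxit = 500000L),
    warning = function(w) {
      if (grepl("fewer than 8|Convergence", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  j <- which.min(abs(fit$lambda - lambda))
  beta <- as.numeric(fit$beta[, j])
  names(beta) <- rownames(fit$beta)
  a0 <- as.numeric(fit$a0[j])
  if (dummy) beta <- beta[names(beta) != ".dummy"]
  selected <- names(beta)[beta != 0]
  structure(list(beta = beta, intercept = a0, lambda = lambda,
                 selected = selected, features = features,
                 intercept_only = length(selected) == 0L),
            class = "lasso_lr")
}

#' Predicted response probabilities from a fitted LASSO logistic model
#'
#' @param object A `lasso_lr` model.
#' @param newdata Feature matrix containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of P(responder).
#' @export
predict.lasso_lr <- function(object, newdata, ...) {
  if (length(object$features) == 0L)
    return(rep(stats::plogis(object$intercept), nrow(newdata)))
  eta <- object$intercept +
    as.numeric(newdata[, object$features, drop = FALSE] %*% object$beta)
  stats::plogis(eta)
}

#' Fit a soft-margin linear SVM
#'
#' Linear support vector machine on the (already standardized) columns passed
#' in — in the pipeline, the features LASSO selected within the same fold.
#' Deterministic given the data and cost.
#'
#' @param X Standardized numeric feature matrix.
#' @param y Binary labels.
#' @param cost Soft-margin cost C, default 1.
#' @return A `linear_svm` list with `w` (weights), `b` (bias), `features`;
#'   decision value = X w + b, positive = responder.
#' @export
fit_linear_svm <- function(X, y, cost = 1) {
  g <- as_positive(y)
  if (length(unique(g)) < 2L) stop("both classes must be present")
  fit <- e1071::svm(X, factor(g, levels = c(FALSE, TRUE)), type = "C-classification",
                    kernel = "linear", cost = cost, scale = FALSE)
  # orient the decision value so positive means responder
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  dv_sign <- if (fit$labels[1L] == 2L) 1 else -1
  structure(list(w = dv_sign * w, b = dv_sign * b, features = colnames(X),
                 cost = cost),
            class = "linear_svm")
}

#' Decision values from a fitted linear SVM
#'
#' @param object A `linear_svm` model.
#' @param newdata Feature matrix containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric decision values; >= 0 predicts responder.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  as.numeric(newdata[, object$features, drop = FALSE] %*% object$w) + object$b
}

#' Leave-one-out cross-validated classification
#'
#' The core evaluation loop: for each training subject i, the univariate
#' filter and the LASSO logistic regression (and, for `classifier = "svm"`,
#' a linear SVM on that fold's LASSO-selected features) are fitted on the
#' remaining n-1 training subjects — never touching subject i — and then
#' score the held-out subject and every validation subject. The training
#' report is computed from the n held-out scores. The validation report
#' averages over fold models: threshold metrics (ACC, SENS, SPEC, PPV, NPV,
#' PHI) are the mean of the per-model metrics, while the validation ROC/AUC
#' is computed from per-subject scores averaged across the fold models.
#'
#' Standardization must already have been fitted on the full training set
#' and applied to both matrices.
#'
#' @param X_train,y_train Standardized training matrix and labels.
#' @param X_val,y_val Standardized validation matrix and labels (optional;
#'   `NULL` skips validation scoring).
#' @param classifier `"lrm"` (LASSO logistic regression) or `"svm"`.
#' @param alpha In-fold filter level, default 0.05.
#' @param lambda_selection Passed to [fit_lasso_lr()].
#' @param inner_folds Inner CV folds for lambda, default 5.
#' @param svm_cost Linear-SVM cost C, default 1.
#' @param decision_threshold Probability threshold for LRM predictions,
#'   default 0.5 (SVM uses decision value >= 0).
#' @param seed Master seed; per-fold seeds are derived from it.
#' @return A `cv_run` list: `fold_results`, `training_report`,
#'   `validation_report`, `validation_mean_metrics` (the averaged threshold
#'   metrics), `classifier`, `seed`.
#' @export
run_loocv <- function(X_train, y_train, X_val = NULL, y_val = NULL,
                      classifier = c("lrm", "svm"), alpha = 0.05,
                      lambda_selection = "min", inner_folds = 5L,
                      svm_cost = 1, decision_threshold = 0.5, seed = 1L) {
  classifier <- match.arg(classifier)
  g <- as_positive(y_train)
  n <- nrow(X_train)
  stopifnot(length(g) == n)
  has_val <- !is.null(X_val)
  score_threshold <- if (classifier == "lrm") decision_threshold else 0

  fold_results <- vector("list", n)
  heldout_scores <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X_train[-i, , drop = FALSE]
    yi <- g[-i]
    if (length(unique(yi)) < 2L)
      stop(sprintf("fold %d leaves a one-class training remainder", i))
    filtered <- univariate_filter(Xi, yi, alpha)
    fold_seed <- derive_seed(seed, sprintf("fold_%03d", i))
    lasso <- fit_lasso_lr(Xi[, filtered, drop = FALSE], yi,
                          lambda_selection, inner_folds, fold_seed)
    if (classifier == "lrm") {
      model <- lasso
    } else if (length(lasso$selected) > 0L) {
      model <- fit_linear_svm(Xi[, lasso$selected, drop = FALSE], yi, svm_cost)
    } else {
      # no feature survived LASSO: constant decision at the prevalence margin
      model <- structure(list(w = numeric(0L), b = stats::qlogis(mean(yi)),
                              features = character(0L), cost = svm_cost),
                         class = "linear_svm")
    }
    heldout_scores[i] <- if (length(model$features) == 0L &&
                             inherits(model, "linear_svm"))
      model$b else predict(model, X_train[i, , drop = FALSE])
    val_scores <- if (has_val) {
      if (length(model$features) == 0L && inherits(model, "linear_svm"))
        rep(model$b, nrow(X_val)) else predict(model, X_val)
    } else NULL
    fold_results[[i]] <- list(
      fold_id = rownames(X_train)[i] %||% i,
      filtered_features = filtered,
      selected_features = lasso$selected,
      lambda = lasso$lambda,
      coefficients = if (classifier == "lrm")
        c(intercept = lasso$intercept, lasso$beta[lasso$selected])
      else c(bias = model$b, stats::setNames(model$w, model$features)),
      heldout_score = heldout_scores[i],
      validation_scores = val_scores)
  }

  training_report <- report_from_scores(heldout_scores, g, score_threshold)

  validation_report <- NULL
  validation_mean_metrics <- NULL
  if (has_val) {
    gv <- as_positive(y_val)
    per_model <- lapply(fold_results, function(fr)
      confusion_metrics(fr$validation_scores >= score_threshold, gv))
    validation_mean_metrics <- sapply(
      c("acc", "sens", "spec", "ppv", "npv", "phi"),
      function(m) mean(vapply(per_model, `[[`, numeric(1L), m), na.rm = TRUE))
    avg_scores <- rowMeans(vapply(fold_results, `[[`,
                                  numeric(nrow(X_val)), "validation_scores"))
    rc <- roc_curve(avg_scores, gv)
    validation_report <- performance_report(
      validation_mean_metrics[["acc"]], validation_mean_metrics[["sens"]],
      validation_mean_metrics[["spec"]], validation_mean_metrics[["ppv"]],
      validation_mean_metrics[["npv"]],
      auc = auc_mw(avg_scores, gv), phi = validation_mean_metrics[["phi"]],
      roc_points = rc[, c("fpr", "tpr")])
  }

  structure(list(fold_results = fold_results,
                 training_report = training_report,
                 validation_report = validation_report,
                 validation_mean_metrics = validation_mean_metrics,
                 classifier = classifier, seed = as.integer(seed),
                 n_train = n),
            class = "cv_run")
}

#' @export
print.cv_run <- function(x, ...) {
  cat(sprintf("<cv_run %s> %d LOOCV folds\n", toupper(x$classifier), x$n_train))
  cat("training:   "); print(x$training_report)
  if (!is.null(x$validation_report)) {
    cat("validation: "); print(x$validation_report)
  }
  invisible(x)
}
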