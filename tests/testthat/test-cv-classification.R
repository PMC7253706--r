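test_that("univariate filter keeps separating features and respects alpha", {
  fx <- make_feature_matrix(20, 20, p = 5, seed = 3L)
  X <- fx$X
  X[, 1] <- rep(c(5, -5), c(20, 20)) + rnorm(40)   # hugely separating
  X[, 2] <- rep(1.5, 40)                           # identical across groups
  expect_warning(sel <- univariate_filter(X, fx$y, alpha = 0.05),
                 "zero-variance")
  expect_true("feat_001" %in% sel)
  expect_false("feat_002" %in% sel)

  suppressWarnings(all_sel <- univariate_filter(X, fx$y, alpha = 1))
  expect_setequal(all_sel, setdiff(colnames(X), "feat_002"))
})

test_that("LASSO logistic regression has the right limits", {
  fx <- make_feature_matrix(20, 20, p = 3, n_info = 2L, delta = 1.5, seed = 6L)
  X <- scale(fx$X)

  # lambda -> infinity: null model predicting the training prevalence
  big <- fit_lasso_lr(X, fx$y, lambda_selection = 50)
  expect_length(big$selected, 0L)
  expect_equal(unname(predict(big, X)[1]), 0.5, tolerance = 1e-6)

  # lambda -> 0: matches unpenalised logistic regression
  tiny <- fit_lasso_lr(X, fx$y, lambda_selection = 1e-7)
  ref <- glm(I(fx$y == "responder") ~ X, family = binomial())
  expect_equal(unname(tiny$beta), unname(coef(ref)[-1]), tolerance = 1e-4)
  expect_equal(tiny$intercept, unname(coef(ref)[1]), tolerance = 1e-4)
})

test_that("the fitted LASSO solution satisfies the KKT conditions", {
  fx <- make_feature_matrix(25, 25, p = 10, n_info = 3L, delta = 1, seed = 8L)
  X <- scale(fx$X)
  y <- as.numeric(fx$y == "responder")
  lambda <- 0.05
  fit <- fit_lasso_lr(X, fx$y, lambda_selection = lambda)
  eta <- fit$intercept + as.numeric(X %*% fit$beta)
  grad <- as.numeric(t(X) %*% (y - plogis(eta))) / nrow(X)
  for (j in seq_along(fit$beta)) {
    if (fit$beta[[j]] == 0) {
      expect_lte(abs(grad[j]), lambda + 1e-6)
    } else {
      expect_lt(abs(grad[j] - lambda * sign(fit$beta[[j]])), 1e-6)
    }
  }
})

test_that("an empty feature set yields a flagged intercept-only model", {
  fx <- make_feature_matrix(10, 10, p = 2, seed = 2L)
  m <- fit_lasso_lr(fx$X[, 0, drop = FALSE], fx$y)
  expect_true(m$intercept_only)
  expect_equal(unname(predict(m, fx$X)[1]), 0.5, tolerance = 1e-10)
})

test_that("linear SVM separates separable data and is label-antisymmetric", {
  set.seed(14)
  X <- cbind(a = c(rnorm(15, 3), rnorm(15, -3)),
             b = c(rnorm(15, 3), rnorm(15, -3)))
  y <- rep(c("responder", "nonresponder"), each = 15)
  m <- fit_linear_svm(X, y, cost = 1)
  expect_true(all((predict(m, X) >= 0) == (y == "responder")))

  flipped <- ifelse(y == "responder", "nonresponder", "responder")
  m2 <- fit_linear_svm(X, flipped, cost = 1)
  expect_equal(m2$w, -m$w, tolerance = 1e-6)
  expect_equal(m2$b, -m$b, tolerance = 1e-6)
})

test_that("SVM decision values agree with an independent QP solver", {
  set.seed(19)
  X <- cbind(u = rnorm(20), v = rnorm(20))
  y <- factor(rep(c(1, 0), 10))
  Xs <- scale(X)
  mine <- fit_linear_svm(Xs, rep(c("responder", "nonresponder"), 10), cost = 1)
  ref <- kernlab::ksvm(Xs, y, type = "C-svc", kernel = "vanilladot",
                       C = 1, scaled = FALSE, kpar = list())
  dv_ref <- kernlab::predict(ref, Xs, type = "decision")
  dv_mine <- predict(mine, Xs)
  # orientations may differ; compare up to sign
  s <- sign(cor(dv_mine, as.numeric(dv_ref)))
  expect_equal(dv_mine, s * as.numeric(dv_ref), tolerance = 1e-4)
})

test_that("LOOCV produces one fold per training subject with no leakage", {
  fx <- make_feature_matrix(8, 8, p = 12, n_info = 3L, delta = 2.2, seed = 21L)
  X <- scale(fx$X)
  # adversarial row: an extreme outlier that flips the filter when included
  X[1, 4:12] <- 8
  cv <- run_loocv(X, fx$y, classifier = "lrm", seed = 5L)
  expect_length(cv$fold_results, 16L)
  expect_s3_class(cv$training_report, "performance_report")

  # fold 1's filter must equal the filter recomputed WITHOUT subject 1 and
  # differ from the filter computed WITH subject 1
  filt_oracle <- suppressWarnings(univariate_filter(X[-1, ], fx$y[-1], 0.05))
  filt_leaky <- suppressWarnings(univariate_filter(X, fx$y, 0.05))
  expect_setequal(cv$fold_results[[1L]]$filtered_features, filt_oracle)
  expect_false(setequal(filt_oracle, filt_leaky))
  # selected features always come from the filtered set
  for (fr in cv$fold_results)
    expect_true(all(fr$selected_features %in% fr$filtered_features))
})

test_that("LOOCV is deterministic given seed and differs across seeds", {
  fx <- make_feature_matrix(7, 7, p = 10, n_info = 2L, delta = 1.2, seed = 30L)
  X <- scale(fx$X)
  a <- run_loocv(X, fx$y, classifier = "lrm", seed = 9L)
  b <- run_loocv(X, fx$y, classifier = "lrm", seed = 9L)
  expect_identical(a$training_report$auc, b$training_report$auc)
  expect_identical(vapply(a$fold_results, `[[`, numeric(1L), "heldout_score"),
                   vapply(b$fold_results, `[[`, numeric(1L), "heldout_score"))
})

test_that("validation metrics average fold models; ROC averages scores", {
  fx <- make_feature_matrix(8, 8, p = 6, n_info = 2L, delta = 2.5, seed = 44L)
  vx <- make_feature_matrix(4, 4, p = 6, n_info = 2L, delta = 2.5, seed = 45L)
  std <- fit_standardizer(fx$X)
  Xtr <- apply_standardizer(fx$X, std)
  Xv <- apply_standardizer(vx$X, std)
  cv <- run_loocv(Xtr, fx$y, Xv, vx$y, classifier = "lrm", seed = 2L)
  per_model_acc <- vapply(cv$fold_results, function(fr)
    mean((fr$validation_scores >= 0.5) == (vx$y == "responder")), numeric(1L))
  expect_equal(cv$validation_report$acc, mean(per_model_acc), tolerance = 1e-12)
  avg <- rowMeans(vapply(cv$fold_results, `[[`, numeric(8L),
                         "validation_scores"))
  expect_equal(cv$validation_report$auc, auc_mw(avg, vx$y), tolerance = 1e-12)
})

test_that("SVM replication restricts each fold to its LASSO selections", {
  fx <- make_feature_matrix(8, 8, p = 8, n_info = 3L, delta = 2, seed = 50L)
  X <- scale(fx$X)
  lrm <- run_loocv(X, fx$y, classifier = "lrm", seed = 7L)
  svm <- run_loocv(X, fx$y, classifier = "svm", seed = 7L)
  for (i in seq_along(svm$fold_results)) {
    coefs <- svm$fold_results[[i]]$coefficients
    expect_setequal(setdiff(names(coefs), "bias"),
                    svm$fold_results[[i]]$selected_features)
    expect_identical(svm$fold_results[[i]]$selected_features,
                     lrm$fold_results[[i]]$selected_features)
  }
})
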