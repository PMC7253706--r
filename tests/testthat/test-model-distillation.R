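# Build a small cv_run whose selections are fully controlled.
fake_cv_run <- function(sel_per_fold, coef_per_fold = NULL) {
  n <- length(sel_per_fold)
  frs <- lapply(seq_len(n), function(i) {
    sel <- sel_per_fold[[i]]
    cf <- if (is.null(coef_per_fold)) stats::setNames(rep(1, length(sel)), sel)
          else coef_per_fold[[i]]
    list(fold_id = i, filtered_features = sel, selected_features = sel,
         lambda = 0.1, coefficients = c(intercept = 0, cf),
         heldout_score = 0.5, validation_scores = NULL)
  })
  structure(list(fold_results = frs, classifier = "lrm", seed = 1L,
                 n_train = n),
            class = "cv_run")
}

test_that("selection frequency counts folds with nonzero coefficients", {
  sel <- c(rep(list(c("a", "b")), 30), rep(list("b"), 14))
  rk <- selection_frequency(fake_cv_run(sel))
  expect_equal(rk$frequency[rk$feature == "a"], 30 / 44, tolerance = 1e-12)
  expect_equal(rk$count[rk$feature == "b"], 44L)
  expect_false("never" %in% rk$feature)
  expect_identical(rk$feature[1L], "b")  # highest frequency first
})

test_that("frequency ranking breaks ties by mean |coefficient| then name", {
  sel <- rep(list(c("small", "big", "alpha")), 4)
  cfs <- rep(list(c(small = 0.1, big = 2, alpha = 0.1)), 4)
  rk <- selection_frequency(fake_cv_run(sel, cfs))
  expect_identical(rk$feature, c("big", "alpha", "small"))
})

test_that("fixed-feature selection applies the strict >50% rule and top-k", {
  rk <- data.frame(feature = c("w", "x", "y", "z"),
                   count = c(35, 27, 25, 13), frequency = c(0.8, 0.6, 0.55, 0.3),
                   mean_abs_coef = 1)
  expect_identical(select_fixed_features(rk, 0.5, 3L), c("w", "x", "y"))

  rk_boundary <- data.frame(feature = c("w", "exact"), count = c(40, 22),
                            frequency = c(0.9, 0.50), mean_abs_coef = 1)
  expect_warning(out <- select_fixed_features(rk_boundary, 0.5, 3L), "only 1")
  expect_identical(out, "w")  # exactly 0.50 is excluded

  rk_none <- data.frame(feature = "w", count = 2, frequency = 0.05,
                        mean_abs_coef = 1)
  expect_warning(out2 <- select_fixed_features(rk_none, 0.5, 3L), "no feature")
  expect_length(out2, 0L)
})

test_that("raising the frequency threshold never grows the fixed set", {
  rk <- data.frame(feature = letters[1:6], count = 1,
                   frequency = c(0.9, 0.7, 0.55, 0.52, 0.3, 0.1),
                   mean_abs_coef = 1)
  sizes <- vapply(c(0.3, 0.5, 0.6, 0.8), function(th)
    length(suppressWarnings(select_fixed_features(rk, th, k = 10L))),
    integer(1L))
  expect_true(all(diff(sizes) <= 0L))
})

test_that("the fixed LRM recovers a strong feature and stays null on noise", {
  set.seed(31)
  aucs_strong <- aucs_null <- numeric(10)
  for (r in 1:10) {
    n_tr <- 40; n_val <- 20
    y_tr <- rep(c("responder", "nonresponder"), each = n_tr / 2)
    y_val <- rep(c("responder", "nonresponder"), each = n_val / 2)
    mk <- function(y, delta) cbind(f_sig = rnorm(length(y)) +
                                     delta * (y == "responder"),
                                   f_noise = rnorm(length(y)))
    Xtr <- mk(y_tr, 2.5); Xval <- mk(y_val, 2.5)
    m <- fit_fixed_lrm(Xtr, y_tr, Xval, y_val, c("f_sig", "f_noise"))
    aucs_strong[r] <- m$validation_report$auc
    Xtr0 <- mk(y_tr, 0); Xval0 <- mk(y_val, 0)
    m0 <- fit_fixed_lrm(Xtr0, y_tr, Xval0, y_val, c("f_sig", "f_noise"))
    aucs_null[r] <- m0$training_report$auc
  }
  expect_gte(mean(aucs_strong > 0.9), 0.8)
  expect_lt(abs(mean(aucs_null) - 0.5), 0.15)
})

test_that("a refitted fixed LRM reproduces identical validation scores", {
  fx <- make_feature_matrix(10, 10, p = 4, n_info = 2L, delta = 1.5, seed = 3L)
  vx <- make_feature_matrix(5, 5, p = 4, n_info = 2L, delta = 1.5, seed = 4L)
  m1 <- fit_fixed_lrm(fx$X, fx$y, vx$X, vx$y, c("feat_001", "feat_002"))
  m2 <- fit_fixed_lrm(fx$X, fx$y, vx$X, vx$y, c("feat_001", "feat_002"))
  expect_identical(m1$validation_report$auc, m2$validation_report$auc)
  expect_identical(coef(m1$fit), coef(m2$fit))
  expect_s3_class(m1$delong, "delong_result")
})

test_that("VIF matches the auxiliary-regression definition", {
  set.seed(12)
  D <- cbind(x1 = rnorm(50), x2 = rnorm(50))
  v <- compute_vif(scale(D))
  expect_equal(unname(v), c(1, 1), tolerance = 0.1)

  Ddup <- cbind(a = D[, 1], b = D[, 1], c = rnorm(50))
  expect_true(is.infinite(compute_vif(Ddup)[["a"]]))

  x1 <- rnorm(60); x2 <- rnorm(60)
  x3 <- x1 + x2 + rnorm(60, sd = 0.3)
  D3 <- cbind(x1 = x1, x2 = x2, x3 = x3)
  v3 <- compute_vif(D3)
  expect_equal(v3[["x3"]], oracle_vif(D3, 3), tolerance = 1e-8)
  expect_equal(v3[["x1"]], oracle_vif(D3, 1), tolerance = 1e-8)
})

test_that("fusion screening removes collinear and insignificant covariates", {
  set.seed(23)
  n <- 40
  y <- rep(c("responder", "nonresponder"), each = n / 2)
  Xr <- cbind(r1 = rnorm(n) + 1.5 * (y == "responder"), r2 = rnorm(n))
  # covariate duplicating a radiomic feature: removed by the VIF pass
  clin <- cbind(dup_r1 = Xr[, "r1"] + rnorm(n, sd = 0.01),
                dose = rnorm(n))
  fm <- build_fusion_model(Xr, clin, y, c("r1", "r2"))
  expect_false("dup_r1" %in% fm$retained_clinical)
  expect_true(any(fm$trace$step == "vif" & fm$trace$covariate == "dup_r1"))
  # radiomic features are never dropped
  expect_true(all(c("r1", "r2") %in% gsub("`", "", rownames(fm$coefficients))))
})

test_that("pure-noise clinical covariates are screened out under the null", {
  set.seed(37)
  removed <- logical(30)
  for (r in 1:30) {
    n <- 50
    y <- rep(c("responder", "nonresponder"), each = n / 2)
    Xr <- cbind(r1 = rnorm(n) + 1.2 * (y == "responder"))
    clin <- cbind(noise_cov = rnorm(n))
    fm <- build_fusion_model(Xr, clin, y, "r1")
    removed[r] <- !("noise_cov" %in% fm$retained_clinical)
  }
  expect_gte(mean(removed), 0.9)
})

test_that("a strongly predictive orthogonal dose covariate is retained", {
  set.seed(41)
  kept <- logical(10)
  for (r in 1:10) {
    n <- 60
    y <- rep(c("responder", "nonresponder"), each = n / 2)
    Xr <- cbind(r1 = rnorm(n) + 0.8 * (y == "responder"))
    clin <- cbind(dose = rnorm(n) + 2.5 * (y == "responder"))
    fm <- build_fusion_model(Xr, clin, y, "r1")
    kept[r] <- "dose" %in% fm$retained_clinical
  }
  expect_gte(mean(kept), 0.8)
})

test_that("fusion with no clinical covariates equals the fixed LRM", {
  fx <- make_feature_matrix(12, 12, p = 3, n_info = 2L, delta = 1.5, seed = 9L)
  vx <- make_feature_matrix(6, 6, p = 3, n_info = 2L, delta = 1.5, seed = 10L)
  feats <- c("feat_001", "feat_002")
  fixed <- fit_fixed_lrm(fx$X, fx$y, vx$X, vx$y, feats)
  fus <- build_fusion_model(fx$X, matrix(numeric(0), nrow(fx$X), 0), fx$y,
                            feats)
  expect_equal(unname(coef(fus$fit)), unname(coef(fixed$fit)),
               tolerance = 1e-10)
})
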