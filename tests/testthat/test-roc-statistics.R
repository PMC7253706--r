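test_that("AUC handles separation, ties and partial concordance", {
  expect_equal(auc_mw(c(0.9, 0.8, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_mw(rep(0.3, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  # 3 of 4 pairs concordant
  expect_equal(auc_mw(c(0.8, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_error(auc_mw(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("trapezoidal ROC area equals the Mann-Whitney AUC to 1e-12", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2L) next
    scores <- rnorm(n)
    if (rep %% 2 == 0) scores <- round(scores, 1)  # force ties
    rc <- roc_curve(scores, y)
    expect_equal(ectradiomics:::trapezoid_auc(rc$fpr, rc$tpr),
                 auc_mw(scores, y), tolerance = 1e-12)
    expect_equal(auc_mw(scores, y), oracle_auc_pairs(scores, y),
                 tolerance = 1e-12)
  }
})

test_that("confusion metrics follow the 2x2-table formulas", {
  perf <- confusion_metrics(rep(TRUE, 4), rep(TRUE, 4))
  expect_equal(perf$acc, 1)
  expect_equal(perf$sens, 1)
  expect_true(is.na(perf$spec))  # no negatives present

  pred <- c(rep(TRUE, 4), FALSE, TRUE, rep(FALSE, 4))
  truth <- c(rep(TRUE, 5), rep(FALSE, 5))
  m <- confusion_metrics(pred, truth)   # TP=4 FN=1 FP=1 TN=4
  expect_equal(m$acc, 0.8)
  expect_equal(m$phi, (16 - 1) / 25)
  expect_equal(m$sens, 0.8)
  expect_equal(m$spec, 0.8)

  const <- confusion_metrics(rep(TRUE, 10), truth)
  expect_equal(const$spec, 0)
  expect_true(is.na(const$npv))
  expect_error(confusion_metrics(c(TRUE, FALSE), TRUE), "mismatch")
})

test_that("phi equals the Pearson correlation of the binary vectors", {
  set.seed(5)
  for (rep in 1:10) {
    pred <- runif(30) > 0.4
    truth <- runif(30) > 0.5
    m <- confusion_metrics(pred, truth)
    if (is.na(m$phi)) next
    expect_equal(m$phi, cor(as.numeric(pred), as.numeric(truth)),
                 tolerance = 1e-12)
  }
})

test_that("paired DeLong is exact on identical scores and tracks jackknife", {
  set.seed(8)
  y <- rep(c(TRUE, FALSE), 10)
  s <- rnorm(20) + y
  same <- delong_paired(s, s, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)

  # single-AUC variance against a leave-one-out jackknife oracle
  comp <- ectradiomics:::delong_components(s, y)
  v_dl <- ectradiomics:::delong_var_single(comp)
  v_jk <- oracle_jackknife_auc_var(s, y)
  expect_lt(abs(v_dl - v_jk) / v_jk, 0.15)
})

test_that("paired DeLong p agrees with a stratified bootstrap", {
  set.seed(30)
  y <- rep(c(TRUE, FALSE), 15)
  a <- rnorm(30) + 1.2 * y
  b <- rnorm(30) + 0.4 * y
  dl <- delong_paired(a, b, y)
  pb <- oracle_bootstrap_delong_p(a, y, b, y, paired = TRUE, B = 2000L)
  expect_lt(abs(dl$p - pb), 0.05)
})

test_that("unpaired DeLong detects separated-vs-chance AUCs", {
  y <- rep(c(TRUE, FALSE), 25)
  sep <- as.numeric(y)                    # AUC exactly 1
  ties <- rep(0, 50)                      # AUC exactly 0.5
  set.seed(12)
  ties <- ties + rnorm(50, sd = 1e-3)     # break exact degeneracy
  dl <- delong_unpaired(sep, y, ties, y)
  expect_lt(dl$p, 0.01)
  pb <- oracle_bootstrap_delong_p(sep, y, ties, y, paired = FALSE, B = 2000L)
  expect_lt(abs(dl$p - pb), 0.05)

  copy <- delong_unpaired(ties, y, ties, y)
  expect_equal(copy$z, 0)
  expect_equal(copy$p, 1)
})

test_that("paired DeLong with zero covariance reduces to the unpaired form", {
  set.seed(41)
  y <- rep(c(TRUE, FALSE), 12)
  a <- rnorm(24) + y
  b <- rnorm(24) + 0.5 * y
  ca <- ectradiomics:::delong_components(a, y)
  cb <- ectradiomics:::delong_components(b, y)
  var_nocov <- ectradiomics:::delong_var_single(ca) +
    ectradiomics:::delong_var_single(cb)
  unp <- delong_unpaired(a, y, b, y)
  expect_equal(unp$var, var_nocov, tolerance = 1e-14)
})

test_that("DeLong results agree with the pROC reference implementation", {
  set.seed(60)
  y <- rep(c(1, 0), 20)
  a <- rnorm(40) + 0.9 * y
  b <- rnorm(40) + 0.3 * y
  dl <- delong_paired(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(dl$p, unname(ref$p.value), tolerance = 1e-9)
  expect_equal(auc_mw(a, y), as.numeric(pROC::auc(pROC::roc(y, a, quiet = TRUE))),
               tolerance = 1e-12)

  y2 <- rep(c(1, 0), 15)
  b2 <- rnorm(30) + 0.3 * y2
  dl2 <- delong_unpaired(a, y, b2, y2)
  ref2 <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                         pROC::roc(y2, b2, quiet = TRUE),
                         method = "delong", paired = FALSE)
  # same structural-components variance, so identical test statistic; the
  # reference converts it with a Welch t rather than the normal, so p values
  # agree only approximately
  expect_equal(dl2$z, unname(ref2$statistic), tolerance = 1e-9)
  expect_equal(dl2$p, unname(ref2$p.value), tolerance = 0.01)
})
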