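# Classification metrics, ROC construction, and DeLong AUC comparisons.

# Coerce labels to logical "positive" (responder = positive class).
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  labels == "responder" | labels == "1" | labels == "TRUE"
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive outscores a random negative, with
#' midrank handling of ties: AUC = P(s+ > s-) + P(s+ = s-)/2. Computed via
#' midranks, which is exactly the Mann-Whitney U statistic normalised by
#' n+ * n-.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (logical, 0/1, or "responder"/"nonresponder").
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  y <- as_positive(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' (FPR, TPR) pairs at every distinct score threshold, from (0,0) to (1,1).
#' Ties are handled by stepping through distinct score values, so the
#' trapezoidal area of the returned polyline equals the Mann-Whitney AUC.
#'
#' @inheritParams auc_mw
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_positive(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[y] >= t) / n1, numeric(1L))
  fpr <- vapply(thr, function(t) sum(scores[!y] >= t) / n0, numeric(1L))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Confusion-matrix metrics and phi coefficient
#'
#' ACC, SENS, SPEC, PPV, NPV and the phi correlation coefficient of the 2x2
#' table of predicted versus true labels. Ratios with a zero denominator are
#' reported as `NA` (missing), never as 0.
#'
#' @param predicted Predicted binary labels.
#' @param labels True binary labels.
#' @return Named list with `acc`, `sens`, `spec`, `ppv`, `npv`, `phi` and the
#'   table counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(predicted, labels) {
  p <- as_positive(predicted); y <- as_positive(labels)
  if (length(p) != length(y)) stop("length mismatch")
  tp <- sum(p & y); fp <- sum(p & !y); tn <- sum(!p & !y); fn <- sum(!p & y)
  n <- tp + fp + tn + fn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  phi_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(acc = ratio(tp + tn, n),
       sens = ratio(tp, tp + fn),
       spec = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn),
       phi = if (phi_den == 0) NA_real_ else (tp * tn - fp * fn) / phi_den,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Build a full performance report from scores and labels
#'
#' Thresholds the scores (probability >= `threshold` for probabilities,
#' decision value >= 0 for margin scores), computes the confusion metrics,
#' the ROC curve, and the Mann-Whitney AUC.
#'
#' @inheritParams auc_mw
#' @param threshold Decision threshold on the scores, default 0.5.
#' @return A [performance_report()].
#' @export
report_from_scores <- function(scores, labels, threshold = 0.5) {
  cm <- confusion_metrics(scores >= threshold, labels)
  rc <- roc_curve(scores, labels)
  performance_report(cm$acc, cm$sens, cm$spec, cm$ppv, cm$npv,
                     auc = auc_mw(scores, labels), phi = cm$phi,
                     roc_points = rc[, c("fpr", "tpr")])
}

# DeLong structural components: V10 (per positive) and V01 (per negative).
# psi(x, y) = 1 if x > y, 1/2 if tied, 0 otherwise; V10_i = mean_j psi,
# V01_j = mean_i psi. Midranks give these in O(n log n).
delong_components <- function(scores, labels) {
  y <- as_positive(labels)
  x <- scores[y]; z <- scores[!y]
  m <- length(x); n <- length(z)
  rall <- rank(c(x, z), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  rz <- rank(z, ties.method = "average")
  v10 <- (rall[seq_len(m)] - rx) / n
  v01 <- 1 - (rall[m + seq_len(n)] - rz) / m
  list(auc = sum(v10) / m, v10 = v10, v01 = v01, m = m, n = n)
}

# Variance of a single AUC from its structural components.
delong_var_single <- function(comp) {
  s10 <- if (comp$m > 1L) stats::var(comp$v10) else 0
  s01 <- if (comp$n > 1L) stats::var(comp$v01) else 0
  s10 / comp$m + s01 / comp$n
}

delong_result <- function(auc1, auc2, var_diff, mode) {
  delta <- auc1 - auc2
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(delta) < .Machine$double.eps) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(var_diff)
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  if (z == 0) p <- 1
  structure(list(auc_1 = auc1, auc_2 = auc2, delta = delta,
                 var = var_diff, z = z, p = p, mode = mode),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("<delong_result %s> AUC %.4f vs %.4f, z = %.3f, p = %.4f\n",
              x$mode, x$auc_1, x$auc_2, x$z, x$p))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score sets on the same subjects (e.g. LRM versus
#' SVM scores), using the structural-components estimate of
#' var(AUC_a - AUC_b) including the covariance term. By convention,
#' identical scores give p = 1.
#'
#' @param scores_a,scores_b Two score vectors on identical subjects.
#' @param labels Shared binary labels.
#' @return A `delong_result` with fields `auc_1`, `auc_2`, `var`, `z`, `p`,
#'   `mode = "paired"`.
#' @export
delong_paired <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("paired DeLong needs equal-length score and label vectors")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- ca$m; n <- ca$n
  if (m == 0L || n == 0L) stop("both classes must be present")
  s10 <- if (m > 1L) stats::cov(cbind(ca$v10, cb$v10)) else matrix(0, 2, 2)
  s01 <- if (n > 1L) stats::cov(cbind(ca$v01, cb$v01)) else matrix(0, 2, 2)
  S <- s10 / m + s01 / n
  var_diff <- S[1L, 1L] + S[2L, 2L] - 2 * S[1L, 2L]
  delong_result(ca$auc, cb$auc, max(var_diff, 0), "paired")
}

#' Unpaired DeLong test for two independent AUCs
#'
#' Compares AUCs computed on disjoint subject sets (e.g. the training-set
#' versus the validation-set ROC curve): the covariance is zero, so
#' z = (AUC_a - AUC_b) / sqrt(var_a + var_b) with each variance from its own
#' structural components.
#'
#' @param scores_a,labels_a First labeled score set.
#' @param scores_b,labels_b Second, independent labeled score set.
#' @return A `delong_result` with `mode = "unpaired"`.
#' @export
delong_unpaired <- function(scores_a, labels_a, scores_b, labels_b) {
  ca <- delong_components(scores_a, labels_a)
  cb <- delong_components(scores_b, labels_b)
  if (ca$m == 0L || ca$n == 0L || cb$m == 0L || cb$n == 0L)
    stop("both classes must be present in each set")
  delong_result(ca$auc, cb$auc,
                delong_var_single(ca) + delong_var_single(cb), "unpaired")
}
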