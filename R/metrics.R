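#' Mann-Whitney ROC AUC
#'
#' The probability that a randomly chosen responder scores higher than a
#' randomly chosen non-responder, with tied pairs credited 0.5. Computed
#' from average ranks, which is exactly the concordant-pair count.
#'
#' @param scores numeric prediction scores (higher = more responder-like).
#' @param labels binary labels in `{0, 100}` (or `{0, 1}`).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(10, 20, 80, 90), c(0, 0, 100, 100))
#' @export
roc_auc <- function(scores, labels) {
  labels <- canonical_labels(labels, length(scores))
  pos <- labels == 100
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    abort("both classes must be present to compute an AUC.")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Discrimination threshold minimizing FP + FN
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted scores plus one sentinel below the minimum and one above the
#' maximum (so "call everyone" and "call no one" are reachable). A sample
#' is called a responder when its score is strictly greater than the
#' threshold. Ties in FP + FN are broken toward the smallest threshold.
#'
#' @inheritParams roc_auc
#' @return The optimal threshold tau.
#' @examples
#' optimal_threshold(c(10, 20, 80, 90), c(0, 0, 100, 100))  # 50
#' @export
optimal_threshold <- function(scores, labels) {
  labels <- canonical_labels(labels, length(scores))
  if (length(unique(labels)) < 2)
    abort("both classes must be present to choose a threshold.")
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  cost <- vapply(cand, function(tau) {
    call_resp <- scores > tau
    sum(call_resp & labels == 0) + sum(!call_resp & labels == 100)
  }, numeric(1))
  cand[which.min(cost)]
}

#' Confusion-matrix metrics at a threshold
#'
#' Thresholds the scores at `tau` (score > tau is a responder call) and
#' reports the classifier-quality panel: ROC AUC, FDR, sensitivity,
#' specificity, accuracy and the Matthews correlation coefficient, along
#' with the confusion counts. FDR here is the per-classifier false
#' discovery fraction FP / (FP + TP) at `tau`, not a multiple-testing
#' rate; it and MCC are defined as 0 when their denominator vanishes.
#'
#' @inheritParams roc_auc
#' @param tau discrimination threshold; defaults to [optimal_threshold()].
#' @return A one-row tibble of class `metrics_report` with columns
#'   `auc`, `tau`, `fdr`, `sn`, `sp`, `acc`, `mcc`, `n`, `tp`, `fp`,
#'   `tn`, `fn`.
#' @examples
#' confusion_metrics(c(10, 20, 80, 90), c(0, 0, 100, 100))
#' @export
confusion_metrics <- function(scores, labels, tau = optimal_threshold(scores, labels)) {
  labels <- canonical_labels(labels, length(scores))
  call_resp <- scores > tau
  tp <- sum(call_resp & labels == 100)
  fp <- sum(call_resp & labels == 0)
  tn <- sum(!call_resp & labels == 0)
  fn <- sum(!call_resp & labels == 100)
  n <- length(scores)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  out <- tibble(
    auc = roc_auc(scores, labels),
    tau = tau,
    fdr = if (tp + fp == 0) 0 else fp / (fp + tp),
    sn = tp / (tp + fn),
    sp = tn / (tn + fp),
    acc = (tp + tn) / n,
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    n = n, tp = tp, fp = fp, tn = tn, fn = fn
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' @rdname confusion_metrics
#' @export
metrics_report <- function(scores, labels) {
  confusion_metrics(scores, labels, optimal_threshold(scores, labels))
}
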