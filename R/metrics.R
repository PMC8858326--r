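# Precision-recall-centric evaluation ------------------------------------

#' Precision-recall curve and average precision
#'
#' Computes precision and recall at every distinct score threshold (tied
#' scores enter the confusion counts together) and summarises the curve by
#' average precision: the step-wise sum of precision times recall increment,
#' with no linear interpolation (linear PR interpolation is optimistic on
#' imbalanced data).
#'
#' @param labels binary labels (both classes required).
#' @param probs numeric scores (finite).
#' @return A list of class `pr_curve` with `thresholds`, `precision`,
#'   `recall`, and `auprc`.
#' @export
pr_curve <- function(labels, probs) {
  check_eval_input(labels, probs)
  ord <- order(probs, decreasing = TRUE)
  y <- labels[ord]
  p <- probs[ord]
  # collapse tied scores: confusion counts at the last index of each tie run
  last <- which(!duplicated(p, fromLast = TRUE))
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  npos <- sum(labels)
  recall <- tp / npos
  precision <- tp / (tp + fp)
  auprc <- sum(diff(c(0, recall)) * precision)
  structure(list(thresholds = p[last], precision = precision,
                 recall = recall, auprc = auprc), class = "pr_curve")
}

#' ROC curve and AUROC
#'
#' True/false positive rates at every distinct threshold; the area is the
#' trapezoidal integral, equal to the normalized Mann-Whitney U statistic
#' (ties counted half).
#'
#' @inheritParams pr_curve
#' @return A list of class `roc_curve` with `thresholds`, `fpr`, `tpr`,
#'   `auroc`.
#' @export
roc_curve <- function(labels, probs) {
  check_eval_input(labels, probs)
  ord <- order(probs, decreasing = TRUE)
  y <- labels[ord]
  p <- probs[ord]
  last <- which(!duplicated(p, fromLast = TRUE))
  tp <- c(0, cumsum(y)[last])
  fp <- c(0, cumsum(1 - y)[last])
  npos <- sum(labels)
  nneg <- length(labels) - npos
  tpr <- tp / npos
  fpr <- fp / nneg
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, p[last]), fpr = fpr, tpr = tpr,
                 auroc = auroc), class = "roc_curve")
}

check_eval_input <- function(labels, probs) {
  if (length(labels) != length(probs)) stop_config("length mismatch")
  if (!all(labels %in% c(0, 1))) stop_config("labels must be binary 0/1")
  if (length(unique(labels)) < 2)
    stop_config("both classes must be present")
  if (!all(is.finite(probs))) stop_config("scores must be finite")
}

# fast average precision used inside the bootstrap loops
average_precision <- function(labels, probs) {
  ord <- order(probs, decreasing = TRUE)
  y <- labels[ord]
  p <- probs[ord]
  last <- which(!duplicated(p, fromLast = TRUE))
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  recall <- tp / sum(labels)
  sum(diff(c(0, recall)) * (tp / (tp + fp)))
}

#' Operating-point metrics under a threshold policy
#'
#' Dichotomises predicted probabilities and reports the confusion counts
#' with precision, recall, specificity, accuracy, F1 and the Brier score.
#' Policies: `fixed` (threshold `tau`), `max_f1` (the threshold maximising
#' F1 over all distinct scores), `full_recall` (the smallest threshold set
#' that captures every case). Predictions at or above the threshold are
#' called positive; tied scores enter together.
#'
#' @inheritParams pr_curve
#' @param policy `"fixed"`, `"max_f1"`, or `"full_recall"`.
#' @param tau threshold for the `fixed` policy.
#' @return A list of class `operating_point`.
#' @export
operating_metrics <- function(labels, probs, policy = c("max_f1", "fixed",
                                                        "full_recall"),
                              tau = 0.5) {
  policy <- match.arg(policy)
  check_eval_input(labels, probs)
  thr <- switch(policy,
    fixed = tau,
    max_f1 = {
      cand <- sort(unique(probs))
      f1 <- vapply(cand, function(t) {
        pred <- probs >= t
        tp <- sum(pred & labels == 1)
        if (tp == 0) return(0)
        prec <- tp / sum(pred)
        rec <- tp / sum(labels == 1)
        2 * prec * rec / (prec + rec)
      }, numeric(1))
      cand[which.max(f1)]
    },
    full_recall = min(probs[labels == 1])
  )
  pred <- probs >= thr
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  structure(list(
    policy = policy, threshold = thr,
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall,
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(labels),
    f1 = if (is.na(precision) || precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall),
    brier = mean((probs - labels)^2)
  ), class = "operating_point")
}

#' Paired stratified bootstrap comparison of AUPRC
#'
#' Tests the one-sided null that model A's AUPRC does not exceed model B's
#' on the same subjects. Cases and controls are resampled separately
#' (stratified), the same resampled indices are applied to both models
#' (paired), and the empirical p-value is
#' `(1 + #\{replicates with delta <= 0\}) / (B + 1)`.
#'
#' @param labels shared binary labels.
#' @param probs_a,probs_b predicted probabilities of the two models for the
#'   same subjects.
#' @param B number of bootstrap replicates.
#' @param seed resampling seed.
#' @return A list of class `auprc_comparison` with the observed AUPRCs, the
#'   replicate delta summary and `p_value`.
#' @export
bootstrap_auprc_pvalue <- function(labels, probs_a, probs_b, B = 2000L,
                                   seed = 1L) {
  check_eval_input(labels, probs_a)
  check_eval_input(labels, probs_b)
  if (B < 100) warning("fewer than 100 bootstrap replicates; ",
                       "the p-value resolution will be coarse")
  idx1 <- which(labels == 1)
  idx0 <- which(labels == 0)
  delta <- numeric(B)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(B)) {
      take <- c(idx1[sample.int(length(idx1), replace = TRUE)],
                idx0[sample.int(length(idx0), replace = TRUE)])
      yb <- labels[take]
      delta[b] <- average_precision(yb, probs_a[take]) -
        average_precision(yb, probs_b[take])
    }
  })
  p <- (1 + sum(delta <= 0)) / (B + 1)
  structure(list(
    auprc_a = average_precision(labels, probs_a),
    auprc_b = average_precision(labels, probs_b),
    B = B, p_value = p,
    delta_mean = mean(delta), delta_q = stats::quantile(delta,
                                                        c(.025, .5, .975))
  ), class = "auprc_comparison")
}

#' Full metric panel for one model's out-of-fold predictions
#'
#' AUROC, AUPRC, Brier, and operating points under all three threshold
#' policies.
#'
#' @param cv a `cv_result` (or any data.frame with `label` and `prob`).
#' @return A list with `auroc`, `auprc`, `brier` and `operating` (one
#'   `operating_point` per policy).
#' @export
evaluate_predictions <- function(cv) {
  labels <- cv$label
  probs <- cv$prob
  list(
    auroc = roc_curve(labels, probs)$auroc,
    auprc = pr_curve(labels, probs)$auprc,
    brier = mean((probs - labels)^2),
    operating = list(
      max_f1 = operating_metrics(labels, probs, "max_f1"),
      full_recall = operating_metrics(labels, probs, "full_recall"),
      fixed = operating_metrics(labels, probs, "fixed", tau = 0.5)
    )
  )
}
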