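#' Rank-based ROC AUC with a DeLong confidence interval
#'
#' The AUC is the Mann-Whitney probability that a randomly chosen case
#' outranks a randomly chosen non-case, ties counted one half; the variance
#' comes from DeLong's placement decomposition.  For a binary marker the
#' AUC equals `(sensitivity + specificity) / 2` exactly.
#'
#' @param predictor numeric marker values (higher = more suspicious of the
#'   event; negate a protective marker before calling).
#' @param outcome binary event indicator; both classes must be present.
#' @param level confidence level.
#' @param label predictor label carried into the result.
#' @return data.frame with `predictor`, `auc`, `ciLow`, `ciHigh`, `n1`, `n0`
#' @examples
#' rocAuc(c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 0))$auc
#' @export
rocAuc <- function(predictor, outcome, level = 0.95, label = "predictor") {
  stopifnot(length(predictor) == length(outcome))
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("outcome must contain both classes")
  cases <- predictor[y == 1]
  controls <- predictor[y == 0]
  # placements: per-case fraction of controls it beats (ties = 1/2), and
  # per-control fraction of cases beating it
  r <- rank(c(cases, controls), ties.method = "average")
  v10 <- (r[seq_len(n1)] - rank(cases, ties.method = "average")) / n0
  v01 <- 1 - (r[n1 + seq_len(n0)] - rank(controls, ties.method = "average")) / n1
  auc <- mean(v10)
  s10 <- if (n1 > 1L) stats::var(v10) else 0
  s01 <- if (n0 > 1L) stats::var(v01) else 0
  se <- sqrt(s10 / n1 + s01 / n0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(predictor = label, auc = auc,
             ciLow = max(0, auc - z * se), ciHigh = min(1, auc + z * se),
             n1 = n1, n0 = n0)
}

#' ROC curve coordinates
#'
#' Plot-ready (false positive rate, true positive rate) pairs over every
#' distinct threshold of the predictor.
#'
#' @inheritParams rocAuc
#' @return data.frame with `threshold`, `fpr`, `tpr`
#' @export
rocCurve <- function(predictor, outcome) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("outcome must be binary with both classes present")
  th <- sort(unique(predictor), decreasing = TRUE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tpr <- vapply(th, function(t) sum(predictor >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(th, function(t) sum(predictor >= t & y == 0) / n0, numeric(1))
  rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
        data.frame(threshold = th, fpr = fpr, tpr = tpr))
}
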