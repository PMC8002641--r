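#' Confusion counts in the S+/S- notation
#'
#' Tallies the four quantities the performance formulas are written in:
#' the number of positive samples S+, negative samples S-, incorrectly
#' predicted positives S-+ (false negatives) and incorrectly predicted
#' negatives S+- (false positives).
#'
#' @param labels 0/1 truth vector.
#' @param calls 0/1 prediction vector of the same length.
#' @return A `confusion_counts` list: `s_plus`, `s_minus`, `s_minus_plus`,
#'   `s_plus_minus`.
#' @export
confusion <- function(labels, calls) {
  if (length(labels) != length(calls)) {
    stop("labels (", length(labels), ") and calls (", length(calls),
         ") differ in length", call. = FALSE)
  }
  structure(list(s_plus = sum(labels == 1L),
                 s_minus = sum(labels == 0L),
                 s_minus_plus = sum(labels == 1L & calls == 0L),
                 s_plus_minus = sum(labels == 0L & calls == 1L)),
            class = "confusion_counts")
}

#' Rank-based AUC
#'
#' Area under the ROC curve by the Mann-Whitney rank statistic; tied
#' probabilities contribute 0.5 per tied positive-negative pair (average
#' ranks). Invariant under strictly monotone transforms of the scores.
#'
#' @param labels 0/1 truth vector.
#' @param probs Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, probs) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes", call. = FALSE)
  r <- rank(probs)                       # average ranks on ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' The five performance metrics
#'
#' Sensitivity, specificity, accuracy and the Matthews correlation
#' coefficient from the S+/S- confusion counts, in the rearranged
#' error-fraction form:
#' \deqn{Sn = 1 - S^{-}_{+}/S^{+}}
#' \deqn{Sp = 1 - S^{+}_{-}/S^{-}}
#' \deqn{Acc = 1 - (S^{-}_{+} + S^{+}_{-})/(S^{+} + S^{-})}
#' \deqn{MCC = \frac{1 - (S^{-}_{+}/S^{+} + S^{+}_{-}/S^{-})}
#'   {\sqrt{(1 + (S^{+}_{-} - S^{-}_{+})/S^{+})(1 + (S^{-}_{+} -
#'   S^{+}_{-})/S^{-})}}}
#' These are algebraically equal to the textbook TP/TN/FP/FN formulas. AUC
#' is added when scores are supplied.
#'
#' @param counts A `confusion_counts`.
#' @param probs Optional score vector (for AUC).
#' @param labels 0/1 truth vector, required with `probs`.
#' @return A `metrics_report` list: `Sn`, `Sp`, `Acc`, `MCC`, `AUC` (`NA`
#'   without scores).
#' @export
metrics <- function(counts, probs = NULL, labels = NULL) {
  sp_ <- counts$s_plus; sm_ <- counts$s_minus
  fn <- counts$s_minus_plus; fp <- counts$s_plus_minus
  if (sp_ == 0L || sm_ == 0L) {
    stop("Sn/Sp/MCC need at least one sample of each class", call. = FALSE)
  }
  acc <- 1 - (fn + fp) / (sp_ + sm_)
  denom <- (1 + (fp - fn) / sp_) * (1 + (fn - fp) / sm_)
  # degenerate tables (all calls one class) have a zero denominator; the
  # usual convention MCC = 0 applies
  mcc <- if (denom <= 0) 0 else (1 - (fn / sp_ + fp / sm_)) / sqrt(denom)
  auc <- if (!is.null(probs)) {
    if (is.null(labels)) stop("labels required with probs", call. = FALSE)
    auc_score(labels, probs)
  } else NA_real_
  structure(list(Sn = 1 - fn / sp_,
                 Sp = 1 - fp / sm_,
                 Acc = acc,
                 MCC = mcc,
                 AUC = auc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Sn=%.4f Sp=%.4f Acc=%.4f MCC=%.4f AUC=%s\n",
              x$Sn, x$Sp, x$Acc, x$MCC,
              if (is.na(x$AUC)) "NA" else sprintf("%.4f", x$AUC)))
  invisible(x)
}

#' Metrics straight from labels, calls and scores
#'
#' Convenience wrapper: [confusion()] then [metrics()].
#'
#' @param labels 0/1 truth vector.
#' @param calls 0/1 prediction vector.
#' @param probs Optional scores for AUC.
#' @return A `metrics_report`.
#' @export
evaluate_predictions <- function(labels, calls, probs = NULL) {
  metrics(confusion(labels, calls), probs = probs, labels = labels)
}
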