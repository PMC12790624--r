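# Classification metrics and the focal loss.

#' Focal loss
#'
#' Mean over labeled genes of `-alpha (1 - p_t)^gamma log(p_t)` with
#' `p_t = p` for positives and `1 - p` for negatives; probabilities are
#' clamped to `[eps, 1 - eps]`. With `gamma = 0`, `alpha = 1` this is binary
#' cross-entropy. Reference parameters: `alpha = 1.0`, `gamma = 1.5`.
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 vector of the same length.
#' @param alpha class-balance weight.
#' @param gamma focusing exponent (>= 0).
#' @param eps probability clamp.
#' @return scalar loss.
#' @export
focal_loss <- function(scores, labels, alpha = 1.0, gamma = 1.5,
                       eps = 1e-7) {
  stopifnot(length(scores) == length(labels), gamma >= 0)
  if (length(scores) == 0L) stop("focal loss: empty labeled set", call. = FALSE)
  p <- pmin(pmax(scores, eps), 1 - eps)
  pt <- ifelse(labels == 1, p, 1 - p)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

#' AUROC, AUPRC and F1
#'
#' AUROC uses the rank (pairwise-ordering) definition with ties counted 0.5;
#' AUPRC is the step-interpolated precision-recall integral with tied score
#' groups processed atomically (order-independent); F1 is computed from the
#' confusion matrix at `threshold`.
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 vector; both classes must be present.
#' @param threshold classification cutoff for F1 (reference value 0.5).
#' @return named numeric vector `c(auroc, auprc, f1)`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L) {
    stop("compute_metrics: both classes must be present", call. = FALSE)
  }
  # AUROC via midranks (ties = 0.5)
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  # AUPRC: descend through tied-score blocks
  o <- order(-scores)
  s <- scores[o]; y <- labels[o]
  blocks <- cumsum(!duplicated(s))
  tp_block <- tapply(y, blocks, sum)
  n_block <- tapply(rep(1L, length(y)), blocks, sum)
  tp_cum <- cumsum(tp_block)
  n_cum <- cumsum(n_block)
  prec <- tp_cum / n_cum
  rec <- tp_cum / npos
  rec_prev <- c(0, rec[-length(rec)])
  auprc <- sum((rec - rec_prev) * prec)
  # F1 at the threshold
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(auroc = auroc, auprc = unname(auprc), f1 = f1)
}
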