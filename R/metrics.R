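#' Confusion matrix counts
#'
#' Positive class = impaired (label 1).
#'
#' @param predictions,labels equal-length 0/1 vectors.
#' @return Named list with integer \code{tp}, \code{fp}, \code{fn},
#'   \code{tn}.
#' @export
confusion_counts <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  stopifnot(all(predictions %in% c(0, 1)), all(labels %in% c(0, 1)))
  list(tp = sum(predictions == 1 & labels == 1),
       fp = sum(predictions == 1 & labels == 0),
       fn = sum(predictions == 0 & labels == 1),
       tn = sum(predictions == 0 & labels == 0))
}

#' Quadratic weighted kappa
#'
#' Chance-corrected agreement with quadratic disagreement weights. For the
#' binary labels used here the quadratic weights reduce it to Cohen's
#' unweighted kappa, \eqn{(p_o - p_e)/(1 - p_e)} with expected agreement
#' \eqn{p_e} from the marginals.
#'
#' @param predictions,labels equal-length integer category vectors.
#' @return Kappa in [-1, 1]; \code{NA} when expected agreement is 1.
#' @export
qwk <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  cats <- sort(unique(c(predictions, labels)))
  k <- length(cats)
  O <- table(factor(predictions, cats), factor(labels, cats))
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  W <- outer(seq_len(k), seq_len(k), function(i, j) (i - j)^2)
  if (k > 1L) W <- W / max(W)
  den <- sum(W * E)
  if (den == 0) return(NA_real_)
  1 - sum(W * O) / den
}

#' Area under the ROC curve
#'
#' Pairwise-concordance form: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, ties counted one half.
#' Computed via the rank (Mann-Whitney) identity, which handles ties by
#' average ranks. Invariant under any strictly increasing score transform.
#'
#' @param scores numeric vector (higher = more impaired-like).
#' @param labels 0/1 vector.
#' @return AUC in [0, 1]; \code{NA} if either class is absent.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate binary predictions
#'
#' Confusion-matrix metrics with impaired (1) as the positive class:
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' accuracy = (TP+TN)/n, specificity = TN/(TN+FP),
#' F = 2PR/(P+R), plus quadratic weighted kappa and, when continuous
#' scores are supplied, AUC. Ratios with a zero denominator are reported as
#' \code{NA} (undefined), never coerced to 0.
#'
#' A \code{weighted} variant of precision/recall/F (class-frequency-weighted
#' one-vs-rest averages, under which precision = recall = accuracy for binary
#' data) is also returned for comparison with reports that use that
#' convention.
#'
#' @param predictions 0/1 vector.
#' @param labels 0/1 vector.
#' @param scores optional numeric scores for AUC.
#' @return An object of class \code{eval_result}: list with
#'   \code{confusion} and the metric fields.
#' @export
evaluate <- function(predictions, labels, scores = NULL) {
  cm <- confusion_counts(predictions, labels)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- rat(cm$tp, cm$tp + cm$fp)
  recall <- rat(cm$tp, cm$tp + cm$fn)
  specificity <- rat(cm$tn, cm$tn + cm$fp)
  n <- length(labels)
  accuracy <- rat(cm$tp + cm$tn, n)
  f_score <- if (is.na(precision) || is.na(recall) ||
                 (precision + recall) == 0) NA_real_
    else 2 * precision * recall / (precision + recall)
  # weighted one-vs-rest averages (the convention under which P = R = acc)
  prec0 <- rat(cm$tn, cm$tn + cm$fn)
  rec0 <- rat(cm$tn, cm$tn + cm$fp)
  w1 <- mean(labels == 1); w0 <- 1 - w1
  wavg <- function(m0, m1) {
    if (is.na(m0) || is.na(m1)) NA_real_ else w0 * m0 + w1 * m1
  }
  out <- list(
    confusion = cm,
    precision = precision, recall = recall, accuracy = accuracy,
    specificity = specificity, f_score = f_score,
    qwk = qwk(predictions, labels),
    auc = if (is.null(scores)) NA_real_ else auc_score(scores, labels),
    weighted = list(precision = wavg(prec0, precision),
                    recall = wavg(rec0, recall),
                    f_score = {
                      f0 <- if (is.na(prec0) || is.na(rec0) ||
                                (prec0 + rec0) == 0) NA_real_
                        else 2 * prec0 * rec0 / (prec0 + rec0)
                      wavg(f0, f_score)
                    }),
    n = n)
  class(out) <- "eval_result"
  out
}

#' @export
print.eval_result <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("n = %d  [TP %d, FP %d, FN %d, TN %d]\n",
              x$n, cm$tp, cm$fp, cm$fn, cm$tn))
  cat(sprintf(
    "precision %.3f  recall %.3f  accuracy %.3f  specificity %.3f\n",
    x$precision, x$recall, x$accuracy, x$specificity))
  cat(sprintf("F %.3f  QWK %.3f  AUC %s\n", x$f_score, x$qwk,
              if (is.na(x$auc)) "-" else sprintf("%.3f", x$auc)))
  invisible(x)
}

metric_names <- function()
  c("precision", "recall", "accuracy", "specificity", "f_score", "qwk", "auc")
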