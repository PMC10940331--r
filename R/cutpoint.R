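#' Fixed-threshold classification rule
#'
#' A cut rule is a threshold on a single score together with an explicit
#' direction: \code{"below"} predicts impairment when score < threshold
#' (ability-like scores such as SSHO2D), \code{"above"} predicts impairment
#' when score > threshold (risk-like composite probabilities). Inequalities
#' are strict, so a patient sitting exactly on the threshold is predicted
#' normal either way.
#'
#' @param threshold numeric threshold on the score scale.
#' @param direction \code{"below"} (impaired if below) or \code{"above"}.
#' @return An object of class \code{cut_rule}.
#' @export
cut_rule <- function(threshold, direction = c("below", "above")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  structure(list(threshold = threshold, direction = direction),
            class = "cut_rule")
}

#' @export
print.cut_rule <- function(x, ...) {
  cat("Cut rule: impaired if score", if (x$direction == "below") "<" else ">",
      format(x$threshold), "\n")
  invisible(x)
}

#' Classify scores by a cut rule
#'
#' @param scores numeric vector without missing values.
#' @param rule a \code{\link{cut_rule}}.
#' @return Integer 0/1 predictions (1 = impaired).
#' @export
classify_by_cut <- function(scores, rule) {
  stopifnot(inherits(rule, "cut_rule"), !anyNA(scores))
  if (rule$direction == "below") as.integer(scores < rule$threshold)
  else as.integer(scores > rule$threshold)
}

#' Count prediction/label mismatches
#'
#' @param predictions,labels equal-length 0/1 vectors.
#' @return Integer number of positions where they differ.
#' @export
count_mismatches <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  sum(predictions != labels)
}

#' Exhaustive search for the mismatch-minimizing cut
#'
#' Evaluates every candidate threshold -- the midpoints between consecutive
#' sorted unique scores plus one sentinel below the minimum and one above
#' the maximum -- in both directions, and returns a rule attaining the
#' global minimum mismatch count. Ties are broken deterministically:
#' direction \code{"below"} preferred, then the smallest threshold. The
#' sentinel rules classify everyone 0 or everyone 1, so the optimum never
#' exceeds min(#impaired, #normal).
#'
#' @param scores numeric vector (at least one value).
#' @param labels 0/1 vector of the same length.
#' @return A list with \code{rule} (a \code{\link{cut_rule}}) and
#'   \code{mismatches}.
#' @export
search_optimal_cut <- function(scores, labels) {
  stopifnot(length(scores) >= 1L, length(scores) == length(labels),
            all(labels %in% c(0, 1)), !anyNA(scores))
  u <- sort(unique(scores))
  cands <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
             u[length(u)] + 1)
  best <- NULL
  for (dir in c("below", "above")) {
    for (th in cands) {
      m <- count_mismatches(classify_by_cut(scores, cut_rule(th, dir)), labels)
      if (is.null(best) || m < best$mismatches)
        best <- list(rule = cut_rule(th, dir), mismatches = m)
    }
  }
  best
}
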