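#' Stratified train/test split
#'
#' Splits indices 1..n into a training and a testing portion with the label
#' proportions preserved. The test size is \code{ceiling(n * (1 - ratio))}
#' (so an 86-patient cohort at ratio 0.8 splits 68/18) and per-class test
#' counts are apportioned by largest remainder.
#'
#' @param labels 0/1 (or categorical) label vector.
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed; identical seed gives an identical split.
#' @return List with integer index vectors \code{train} and \code{test}
#'   (disjoint, exhaustive).
#' @export
split_cohort <- function(labels, ratio = 0.8, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  n <- length(labels)
  n_test <- ceiling(n * (1 - ratio))
  cls <- unique(labels)
  n_c <- vapply(cls, function(cl) sum(labels == cl), 0L)
  quota <- n_c * n_test / n
  base <- floor(quota)
  extra <- n_test - sum(base)
  ord <- order(quota - base, n_c, decreasing = TRUE)
  take <- base
  if (extra > 0) take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
  if (any(take >= n_c) || any(take < 1))
    stop("stratified split impossible: a class would be absent from the ",
         "training or testing portion")
  set.seed(seed)
  test <- unlist(lapply(seq_along(cls), function(i) {
    ix <- which(labels == cls[i])
    sample(ix, take[i])
  }))
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Bootstrap evaluation of a classifier
#'
#' Repeats, \code{B} times: resample the n patients with replacement
#' (keeping the original sample size), split the resample into stratified
#' 80/20 train/test portions, grid-search-train the classifier on the
#' training portion with stratified 5-fold cross-validation, and evaluate
#' on the test portion. Reports the mean and SD of each metric over the
#' replications; metrics undefined in a replication (e.g. precision with no
#' predicted positives) are skipped, with skip counts recorded.
#'
#' Because a bootstrap resample contains duplicates, the same patient can
#' land in both portions of the split; that leakage is part of the protocol
#' being reproduced, and the summary should be read as a stability measure
#' rather than out-of-sample error.
#'
#' @param x numeric feature matrix (n rows).
#' @param y 0/1 labels.
#' @param spec a \code{\link{model_spec}} or model name.
#' @param B number of bootstrap replications (default 100).
#' @param seed integer seed driving the whole procedure.
#' @param ratio training fraction (default 0.8).
#' @param folds CV folds inside the grid search (default 5).
#' @return An object of class \code{bootstrap_summary}: list with
#'   \code{mean}, \code{sd}, \code{n_used}, \code{skipped}, \code{B},
#'   \code{seed}, \code{model}, and the per-replication \code{draws} matrix.
#' @export
bootstrap_evaluate <- function(x, y, spec, B = 100L, seed = 1L,
                               ratio = 0.8, folds = 5L) {
  if (is.character(spec)) spec <- model_spec(spec)
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(B >= 1L, nrow(x) == length(y))
  n <- nrow(x)
  set.seed(seed)
  rep_seeds <- sample.int(2^30, B)
  mets <- metric_names()
  draws <- matrix(NA_real_, B, length(mets), dimnames = list(NULL, mets))
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (length(unique(yb)) < 2L) next   # degenerate resample, skip
    sp <- tryCatch(split_cohort(yb, ratio = ratio, seed = rep_seeds[b] + 1L),
                   error = function(e) NULL)
    if (is.null(sp)) next               # class too rare to stratify, skip
    fit <- grid_search_train(spec, x[idx[sp$train], , drop = FALSE],
                             yb[sp$train], folds = folds,
                             seed = rep_seeds[b] + 2L)
    pr <- predict(fit, x[idx[sp$test], , drop = FALSE])
    ev <- evaluate(pr$labels, yb[sp$test], scores = pr$scores)
    draws[b, ] <- unlist(ev[mets])
  }
  structure(list(
    mean = colMeans(draws, na.rm = TRUE),
    sd = apply(draws, 2, stats::sd, na.rm = TRUE),
    n_used = colSums(!is.na(draws)),
    skipped = colSums(is.na(draws)),
    draws = draws, B = B, seed = seed, model = spec$name),
    class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("Bootstrap evaluation:", x$model, "-", x$B, "replications (seed",
      paste0(x$seed, ")\n"))
  tab <- data.frame(mean = round(x$mean, 3), sd = round(x$sd, 3),
                    used = x$n_used, skipped = x$skipped)
  print(tab)
  invisible(x)
}
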