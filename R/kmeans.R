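#' KMeans elbow exploration
#'
#' Runs k-means for k = 1..k_max and records the inertia (total
#' within-cluster sum of squared distances to the nearest center) per k, for
#' the elbow heuristic. For each k the best of several random starts is
#' kept, plus a warm start seeded from the previous solution's centers
#' augmented with the worst-fitted point, which guarantees the inertia curve
#' is non-increasing in k.
#'
#' @param x numeric data matrix (n rows, n >= k_max).
#' @param k_max largest cluster count (default 10).
#' @param seed integer seed.
#' @param k_select cluster count at which labels are returned (default 3).
#' @param nstart random restarts per k (default 10).
#' @return List with \code{inertia} (named numeric, k = 1..k_max),
#'   \code{labels} (cluster assignment at \code{k_select}) and
#'   \code{k_select}.
#' @export
kmeans_elbow <- function(x, k_max = 10L, seed = 1L, k_select = 3L,
                         nstart = 10L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= k_max, k_max >= 1L, k_select <= k_max)
  set.seed(seed)
  inertia <- numeric(k_max)
  labels <- NULL
  prev <- NULL
  for (k in seq_len(k_max)) {
    if (k == nrow(x) && !anyDuplicated(x)) {
      # every point its own center: inertia exactly zero
      inertia[k] <- 0
      if (k == k_select) labels <- seq_len(nrow(x))
      prev <- NULL
      next
    }
    km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = nstart,
                                         iter.max = 100))
    if (!is.null(prev)) {
      # warm start: previous centers plus the point they fit worst
      d2 <- rowSums((x - prev$centers[prev$cluster, , drop = FALSE])^2)
      init <- rbind(prev$centers, x[which.max(d2), , drop = FALSE])
      init <- init[!duplicated(init), , drop = FALSE]
      if (nrow(init) == k) {
        km2 <- suppressWarnings(stats::kmeans(x, centers = init,
                                              iter.max = 100))
        if (km2$tot.withinss < km$tot.withinss) km <- km2
      }
    }
    inertia[k] <- km$tot.withinss
    prev <- km
    if (k == k_select) labels <- km$cluster
  }
  list(inertia = stats::setNames(inertia, seq_len(k_max)),
       labels = labels, k_select = k_select)
}
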