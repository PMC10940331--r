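#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \deqn{\alpha = \frac{k}{k-1}\Big(1 - \frac{\sum_j s_j^2}{s_T^2}\Big)}
#' where \eqn{s_j^2} are item variances and \eqn{s_T^2} the variance of the
#' total score, computed over rows with complete data.
#'
#' @param x numeric matrix, rows = persons, columns = items; items
#'   (columns) containing missing values are dropped, so the coefficient is
#'   computed over the completely observed items.
#' @return Alpha, or \code{NA} when fewer than 2 complete items, fewer than
#'   2 persons, or zero total-score variance.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  x <- x[, colSums(is.na(x)) == 0L, drop = FALSE]
  k <- ncol(x)
  if (k < 2L || nrow(x) < 2L) return(NA_real_)
  v_tot <- stats::var(rowSums(x))
  if (v_tot <= 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / v_tot)
}

#' Summarize a cohort
#'
#' Descriptive tables in the shape a screening study reports: group counts,
#' number-correct score means/SDs split by impairment, gender, race,
#' education and income, pairwise Pearson correlations between labels,
#' demographics and the DCCS/PSM number-correct scores, and per-instrument
#' Cronbach's alpha.
#'
#' @param cohort a \code{\link{cog_cohort}}.
#' @return A list with elements \code{counts}, \code{group_means},
#'   \code{correlations}, \code{alpha}, \code{n}. With a single patient the
#'   variance-based entries are \code{NA} and flagged via
#'   \code{variance_defined = FALSE}.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cog_cohort"))
  p <- cohort$patients
  n <- nrow(p)
  group_vars <- c("impaired", "gender", "race", "education", "income")
  counts <- lapply(group_vars, function(v) as.data.frame(table(p[[v]])))
  names(counts) <- group_vars
  out <- list(n = n, counts = counts, variance_defined = n >= 2L)
  nc <- vapply(cohort$responses, function(m) rowSums(m, na.rm = TRUE),
               numeric(n))
  if (n == 1L) nc <- matrix(nc, nrow = 1, dimnames = list(NULL, instrument_names()))
  if (n < 2L) {
    out$group_means <- NULL
    out$correlations <- NULL
    out$alpha <- setNames(rep(NA_real_, 5), instrument_names())
    return(out)
  }
  out$group_means <- lapply(setNames(group_vars, group_vars), function(v) {
    g <- p[[v]]
    do.call(rbind, lapply(split(seq_len(n), g), function(ix) {
      data.frame(group = g[ix[1]], n = length(ix),
                 t(colMeans(nc[ix, , drop = FALSE])),
                 stringsAsFactors = FALSE)
    }))
  })
  num <- data.frame(
    impaired = p$impaired,
    education = suppressWarnings(as.numeric(p$education)),
    race = encode_demographic(p$race, "race"),
    income = encode_demographic(p$income, "income"),
    age = p$age,
    gender = encode_demographic(p$gender, "gender"),
    PSM = nc[, "PSM"], DCCS = nc[, "DCCS"])
  out$correlations <- stats::cor(num, use = "pairwise.complete.obs")
  out$alpha <- vapply(cohort$responses, cronbach_alpha, 0)
  out
}
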