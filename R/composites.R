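#' Classical instrument scores
#'
#' Number-correct per instrument (observed 1s; missing items do not count)
#' and, for the timed instruments, the accuracy rate = number correct
#' divided by total response time (1/seconds). DCCS and ARW enter the
#' composite models through their accuracy rates; PSM, MFS and NSM through
#' number-correct.
#'
#' @param cohort a \code{\link{cog_cohort}}.
#' @return A data frame with per-patient columns \code{nc_<instr>} (number
#'   correct), \code{obs_<instr>} (observed item count), \code{rate_dccs},
#'   \code{rate_arw}, \code{rate_psm}, \code{rt_dccs}, \code{rt_psm},
#'   \code{rt_arw} (seconds) and \code{age}.
#' @export
classical_scores <- function(cohort) {
  stopifnot(inherits(cohort, "cog_cohort"))
  if (any(unlist(cohort$rt) <= 0)) stop("response times must be positive")
  n <- length(cohort)
  out <- data.frame(row.names = seq_len(n))
  for (nm in instrument_names()) {
    m <- cohort$responses[[nm]]
    out[[paste0("nc_", tolower(nm))]] <- as.numeric(rowSums(m, na.rm = TRUE))
    out[[paste0("obs_", tolower(nm))]] <- as.integer(rowSums(!is.na(m)))
  }
  for (nm in rt_instruments()) {
    lnm <- tolower(nm)
    out[[paste0("rt_", lnm)]] <- cohort$rt[[nm]]
    out[[paste0("rate_", lnm)]] <- out[[paste0("nc_", lnm)]] / cohort$rt[[nm]]
  }
  out$age <- cohort$patients$age
  out
}

#' Construct a composite-score model
#'
#' A composite score is the logistic transform of a linear function of a
#' small set of score features,
#' \eqn{P = \sigma(\beta_0 + \sum_k \beta_k x_k)}. The linear part is fitted
#' by ordinary least squares of the 0/1 impairment label on the features
#' (\code{\link{fit_composite}}), matching how the published coefficient
#' table was produced; the logistic transform is applied afterwards.
#'
#' @param name model name.
#' @param intercept numeric intercept.
#' @param coef named numeric coefficients; names must match score-bundle
#'   columns.
#' @param rt_unit unit of any response-time features ("s" or "ms").
#' @return An object of class \code{composite_model}.
#' @export
composite_model <- function(name, intercept, coef, rt_unit = "s") {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coef), !is.null(names(coef)), all(nzchar(names(coef))))
  structure(list(name = name, intercept = unname(intercept), coef = coef,
                 rt_unit = rt_unit),
            class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat("Composite model", x$name, "\n  intercept:", format(x$intercept), "\n")
  for (nm in names(x$coef))
    cat(sprintf("  %-10s %s\n", nm, format(x$coef[[nm]])))
  invisible(x)
}

#' Fit a composite model by ordinary least squares
#'
#' Regresses the 0/1 impairment label on the feature columns by OLS and
#' wraps the coefficients as a \code{\link{composite_model}}. The label is
#' deliberately treated as a numeric response (a linear probability model)
#' with the logistic transform applied only at score time; this is the
#' construction under which the published coefficients and composite values
#' are mutually consistent, and it differs from logistic regression.
#'
#' @param features data frame or matrix of numeric features (no missing
#'   values).
#' @param labels 0/1 vector, length \code{nrow(features)}.
#' @param name model name.
#' @return A \code{\link{composite_model}}.
#' @export
fit_composite <- function(features, labels, name = "composite") {
  x <- as.matrix(features)
  stopifnot(nrow(x) == length(labels), all(labels %in% c(0, 1)))
  if (anyNA(x)) stop("features contain missing values")
  if (nrow(x) <= ncol(x)) stop("need more patients than features")
  X <- cbind(`(Intercept)` = 1, x)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear feature(s): ",
         paste(drop_cols, collapse = ", "))
  }
  beta <- qr.coef(qx, as.numeric(labels))
  composite_model(name, intercept = beta[1],
                  coef = stats::setNames(beta[-1], colnames(x)))
}

#' Apply a composite model to a score bundle
#'
#' Computes \eqn{P = \sigma(\beta_0 + \sum_k \beta_k x_k)} per patient,
#' with \eqn{\sigma(f) = e^f / (1 + e^f)}.
#'
#' @param model a \code{\link{composite_model}}.
#' @param scores data frame containing every feature the model names.
#' @param rt_unit unit of the bundle's response-time columns; must match the
#'   model's \code{rt_unit} when the model uses response-time features.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
apply_composite <- function(model, scores, rt_unit = "s") {
  stopifnot(inherits(model, "composite_model"))
  miss <- setdiff(names(model$coef), names(scores))
  if (length(miss) > 0L)
    stop("score bundle is missing feature(s): ", paste(miss, collapse = ", "))
  uses_rt <- any(grepl("^rt_", names(model$coef)))
  if (uses_rt && !identical(model$rt_unit, rt_unit))
    stop("model ", model$name, " expects response times in ", model$rt_unit,
         " but the bundle is in ", rt_unit)
  f <- model$intercept
  for (nm in names(model$coef)) f <- f + model$coef[[nm]] * scores[[nm]]
  stats::plogis(f)
}
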