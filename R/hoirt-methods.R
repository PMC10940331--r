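#' @export
print.hoirt <- function(x, ...) {
  cat("Higher-order 2PL IRT model (MCMC)\n")
  cat("  patients:", x$n, "  items:", x$J,
      "  domains:", paste(x$config$domains, collapse = ", "), "\n")
  cat("  chain: ", x$config$n_iter, " iterations (",
      x$config$n_burn, " burn-in, thin ", x$config$thin, "), ",
      x$n_retained, " retained draws\n", sep = "")
  cat("  loadings (lambda):",
      paste(sprintf("%s=%.3f", names(x$lambda), x$lambda), collapse = ", "),
      "\n")
  invisible(x)
}

#' Summary of a fitted higher-order IRT model
#'
#' Reports posterior-mean loadings, item-parameter ranges, per-block
#' acceptance rates, and a split-chain stability check: the absolute
#' difference between first- and second-half posterior means of each loading
#' and of the average general ability (large values flag a chain that has
#' not settled).
#'
#' @param object a fitted \code{\link{hoirt}} model.
#' @param ... unused.
#' @export
summary.hoirt <- function(object, ...) {
  out <- list(lambda = object$lambda,
              a_range = range(object$items$a),
              b_range = range(object$items$b),
              acceptance = object$acceptance,
              n = object$n, J = object$J, config = object$config)
  if (!is.null(object$chains)) {
    R <- object$n_retained
    h1 <- seq_len(floor(R / 2)); h2 <- setdiff(seq_len(R), h1)
    out$split_lambda <- abs(colMeans(object$chains$lambda[h1, , drop = FALSE]) -
                            colMeans(object$chains$lambda[h2, , drop = FALSE]))
    mg <- rowMeans(object$chains$theta_g)
    out$split_theta_g <- abs(mean(mg[h1]) - mean(mg[h2]))
  }
  class(out) <- "summary.hoirt"
  out
}

#' @export
print.summary.hoirt <- function(x, ...) {
  cat("Higher-order 2PL IRT fit:", x$n, "patients,", x$J, "items\n")
  cat("  lambda:", paste(sprintf("%s=%.3f", names(x$lambda), x$lambda),
                         collapse = ", "), "\n")
  cat(sprintf("  a in [%.3f, %.3f], b in [%.3f, %.3f]\n",
              x$a_range[1], x$a_range[2], x$b_range[1], x$b_range[2]))
  cat(sprintf("  acceptance: a %.2f, b %.2f, theta %s, lambda %s\n",
              x$acceptance$a, x$acceptance$b,
              paste(sprintf("%.2f", x$acceptance$theta), collapse = "/"),
              paste(sprintf("%.2f", x$acceptance$lambda), collapse = "/")))
  if (!is.null(x$split_lambda))
    cat(sprintf("  split-chain |diff|: lambda max %.3f, mean theta_g %.3f\n",
                max(x$split_lambda), x$split_theta_g))
  invisible(x)
}

#' Extract posterior-mean parameters
#'
#' @param object a fitted \code{\link{hoirt}} model.
#' @param ... unused.
#' @return Named vector of item discriminations, difficulties and loadings.
#' @export
coef.hoirt <- function(object, ...) {
  c(stats::setNames(object$items$a, paste0("a", seq_len(object$J))),
    stats::setNames(object$items$b, paste0("b", seq_len(object$J))),
    stats::setNames(object$lambda, paste0("lambda_", names(object$lambda))))
}

#' Predict from a fitted higher-order IRT model
#'
#' With \code{type = "scores"} (default) returns the EAP ability scores of
#' the training patients (see \code{\link{eap_scores}}). With
#' \code{type = "prob"} returns the n x J matrix of response probabilities
#' evaluated at the posterior-mean parameters. With \code{newdata}, scores
#' new patients by rerunning the ability chain with item parameters and
#' loadings fixed at their posterior means.
#'
#' @param object a fitted \code{\link{hoirt}} model.
#' @param newdata optional response matrix for new patients.
#' @param type \code{"scores"} or \code{"prob"}.
#' @param n_iter,n_burn chain controls for scoring \code{newdata}.
#' @param seed RNG seed for scoring \code{newdata}.
#' @param ... unused.
#' @export
predict.hoirt <- function(object, newdata = NULL,
                          type = c("scores", "prob"),
                          n_iter = 1500L, n_burn = 500L, seed = 1L, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "scores") return(eap_scores(object))
    Th <- object$theta_d[, as.integer(object$items$domain), drop = FALSE]
    return(stats::plogis(sweep(Th, 2, object$items$a, `*`) -
                           rep(object$items$a * object$items$b,
                               each = object$n)))
  }
  refit <- hoirt(newdata, domains = object$items$domain,
                 n_iter = n_iter, n_burn = n_burn, seed = seed,
                 fix_items = list(a = object$items$a, b = object$items$b),
                 store_chains = FALSE)
  if (type == "scores") eap_scores(refit) else predict(refit, type = "prob")
}

#' Simulate response matrices from a fitted model
#'
#' @param object a fitted \code{\link{hoirt}} model.
#' @param nsim number of replicate response matrices.
#' @param seed integer seed.
#' @param n patients per replicate (default: the fitted cohort size).
#' @param ... unused.
#' @return A list of \code{nsim} simulation lists as returned by
#'   \code{\link{simulate_hoirt}}.
#' @export
simulate.hoirt <- function(object, nsim = 1, seed = 1L, n = object$n, ...) {
  items <- data.frame(a = object$items$a, b = object$items$b,
                      domain = as.integer(object$items$domain))
  lapply(seq_len(nsim), function(k)
    simulate_hoirt(items, object$lambda, n, seed = seed + k - 1L))
}

#' Response residuals at the posterior mean
#'
#' Observed minus expected response probability, NA where the response is
#' missing.
#'
#' @param object a fitted \code{\link{hoirt}} model.
#' @param ... unused.
#' @export
residuals.hoirt <- function(object, ...) {
  object$responses - predict(object, type = "prob")
}

#' Trace and item plots for a fitted model
#'
#' Draws loading traces (when chains are stored) and the scatter of item
#' difficulty against discrimination.
#'
#' @param x a fitted \code{\link{hoirt}} model.
#' @param ... passed to \code{plot}.
#' @export
plot.hoirt <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  if (!is.null(x$chains)) {
    graphics::matplot(x$chains$lambda, type = "l", lty = 1,
                      xlab = "retained draw", ylab = "lambda",
                      main = "Loading traces", ...)
  } else {
    graphics::plot.new(); graphics::title("chains not stored")
  }
  graphics::plot(x$items$b, x$items$a, col = as.integer(x$items$domain),
                 xlab = "difficulty b", ylab = "discrimination a",
                 main = "Item parameters (EAP)", ...)
  invisible(x)
}
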