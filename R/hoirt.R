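#' Two-parameter logistic item response function
#'
#' Probability of a correct response under the 2PL model,
#' \deqn{P(y = 1 \mid \theta) = \frac{1}{1 + e^{-a(\theta - b)}}}
#' with discrimination \eqn{a > 0}, difficulty \eqn{b} and ability
#' \eqn{\theta} on the same latent scale. No 1.7 scaling constant is used.
#'
#' @param a discrimination, strictly positive (recycled).
#' @param b difficulty (recycled).
#' @param theta ability (recycled).
#' @return Probabilities strictly inside (0, 1).
#' @examples
#' irf_2pl(1, 0, 0)      # 0.5
#' irf_2pl(2, 0, 1)      # 1/(1+exp(-2))
#' @export
irf_2pl <- function(a, b, theta) {
  if (any(a <= 0)) stop("discrimination a must be > 0")
  stats::plogis(a * (theta - b))
}

# log(1 + exp(x)), stable for large |x|
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Bernoulli log-likelihood cells: y*eta - log(1+exp(eta)), zero where unobserved.
# y0 must have NA replaced by 0 and mask is 1 for observed cells.
ll_cells <- function(eta, y0, mask) (y0 * eta - softplus(eta)) * mask

#' Observed-data log-likelihood of a higher-order 2PL model
#'
#' Sum over observed (non-missing) cells of the Bernoulli log-likelihood
#' under \code{\link{irf_2pl}}, each item evaluated at the ability of its
#' domain. Optionally adds the log prior density of the abilities under the
#' higher-order structure \eqn{\theta_d = \lambda_d \theta_g + \epsilon_d},
#' \eqn{\epsilon_d \sim N(0, 1-\lambda_d^2)}, \eqn{\theta_g \sim N(0,1)}.
#'
#' @param responses n x J matrix of 0/1/NA item responses.
#' @param items data frame with columns \code{a}, \code{b} and \code{domain}
#'   (integer in \code{1..D}).
#' @param lambda numeric vector of D domain loadings in (0, 1).
#' @param theta_g length-n general abilities.
#' @param theta_d n x D domain abilities.
#' @param include_prior if \code{TRUE}, add the ability prior log density.
#' @return A single finite number.
#' @export
response_loglik <- function(responses, items, lambda, theta_g, theta_d,
                            include_prior = FALSE) {
  y <- as.matrix(responses)
  theta_d <- as.matrix(theta_d)
  if (ncol(y) != nrow(items)) stop("responses and items disagree on J")
  if (nrow(y) != nrow(theta_d) || nrow(y) != length(theta_g))
    stop("responses and abilities disagree on n")
  mask <- !is.na(y)
  y0 <- ifelse(mask, y, 0)
  Th <- theta_d[, items$domain, drop = FALSE]
  eta <- sweep(Th, 2, items$a, `*`) - rep(items$a * items$b, each = nrow(y))
  ll <- sum(ll_cells(eta, y0, mask * 1))
  if (include_prior) {
    sdd <- sqrt(1 - lambda^2)
    for (d in seq_along(lambda))
      ll <- ll + sum(stats::dnorm(theta_d[, d], lambda[d] * theta_g, sdd[d],
                                  log = TRUE))
    ll <- ll + sum(stats::dnorm(theta_g, 0, 1, log = TRUE))
  }
  ll
}

#' Simulate responses from a higher-order 2PL model
#'
#' Draws \eqn{\theta_g \sim N(0,1)},
#' \eqn{\theta_d = \lambda_d\theta_g + \sqrt{1-\lambda_d^2}\,\epsilon} with
#' standard normal \eqn{\epsilon} (so every domain ability has unit marginal
#' variance), then Bernoulli responses from \code{\link{irf_2pl}}.
#'
#' @param items data frame with columns \code{a}, \code{b}, \code{domain}.
#' @param lambda domain loadings in (0, 1]; \code{lambda = 1} makes the
#'   domain ability equal the general ability.
#' @param n number of patients.
#' @param seed integer RNG seed.
#' @return List with \code{responses} (n x J 0/1 matrix), \code{theta_g},
#'   \code{theta_d}.
#' @export
simulate_hoirt <- function(items, lambda, n, seed = 1L) {
  stopifnot(n >= 1, all(items$a > 0), all(lambda > 0), all(lambda <= 1))
  D <- max(items$domain)
  stopifnot(length(lambda) == D)
  set.seed(seed)
  theta_g <- stats::rnorm(n)
  theta_d <- sapply(seq_len(D), function(d)
    lambda[d] * theta_g + sqrt(1 - lambda[d]^2) * stats::rnorm(n))
  theta_d <- matrix(theta_d, nrow = n)
  Th <- theta_d[, items$domain, drop = FALSE]
  p <- stats::plogis(sweep(Th, 2, items$a, `*`) -
                       rep(items$a * items$b, each = n))
  y <- matrix(stats::rbinom(n * nrow(items), 1, p), nrow = n)
  list(responses = y, theta_g = theta_g, theta_d = theta_d)
}

#' Fit a higher-order 2PL IRT model by MCMC
#'
#' Metropolis-within-Gibbs sampler for the hierarchical 2PL model in which
#' each item measures one content domain and the domain abilities load on a
#' single general ability:
#' \deqn{P(y_{ij}=1) = \mathrm{logit}^{-1}\{a_j(\theta_{i,d(j)} - b_j)\},\quad
#'       \theta_{i,d} = \lambda_d \theta_{i,g} + \epsilon_{i,d},}
#' \eqn{\epsilon_{i,d} \sim N(0, 1-\lambda_d^2)}, \eqn{\theta_g \sim N(0,1)}.
#' The unit-variance constraint identifies the scale and \eqn{\lambda_d \in
#' (0,1)} resolves the reflection invariance. The general-ability posterior
#' mean is the overall score (SSHO with five domains, SSHO2D with two).
#'
#' Priors: \eqn{\log a \sim N(0, 0.5^2)}, \eqn{b \sim N(0, 2^2)},
#' \eqn{\lambda_d \sim U(0,1)}. The general ability is drawn from its exact
#' normal full conditional; items, domain abilities and loadings use Gaussian
#' random-walk proposals whose step sizes adapt during burn-in toward a
#' 20--50\% acceptance rate and are frozen afterwards. Missing responses are
#' treated as missing at random and skipped in the likelihood.
#'
#' @param responses n x J matrix of 0/1/NA responses (NA = not administered).
#' @param domains length-J factor or integer vector assigning items to
#'   content domains.
#' @param n_iter total MCMC iterations.
#' @param n_burn burn-in iterations discarded (must be < \code{n_iter}).
#' @param thin retain every \code{thin}-th post-burn-in draw.
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical chains.
#' @param priors list overriding \code{log_a_mean}, \code{log_a_sd},
#'   \code{b_mean}, \code{b_sd}.
#' @param fix_items optional list with vectors \code{a}, \code{b}: hold item
#'   parameters fixed (not sampled), e.g. for scoring new patients with a
#'   calibrated bank.
#' @param store_chains keep retained draws of all parameters (needed by
#'   \code{\link{eap_scores}} cross-checks; on by default).
#' @return An object of class \code{hoirt}; see
#'   \code{\link{eap_scores}}, \code{\link{summary.hoirt}},
#'   \code{\link{predict.hoirt}}.
#' @export
hoirt <- function(responses, domains, n_iter = 5000L, n_burn = 2000L,
                  thin = 1L, seed = 1L, priors = list(),
                  fix_items = NULL, store_chains = TRUE) {
  y <- as.matrix(responses)
  n <- nrow(y); J <- ncol(y)
  if (is.null(domains)) domains <- attr(responses, "domain")
  dom_f <- if (is.factor(domains)) domains else factor(domains)
  stopifnot(length(dom_f) == J, n_iter > n_burn, n_burn >= 0, thin >= 1)
  dom <- as.integer(dom_f)
  D <- nlevels(dom_f)
  mask <- (!is.na(y)) * 1
  if (any(rowSums(mask) == 0))
    stop("every patient must have at least one observed response")
  for (d in seq_len(D)) {
    if (sum(mask[, dom == d]) == 0)
      stop("domain ", levels(dom_f)[d], " has zero observed responses")
    if (sum(dom == d) < 2L)
      stop("domain ", levels(dom_f)[d], " has fewer than 2 items")
  }
  y0 <- ifelse(mask == 1, y, 0)
  pr <- utils::modifyList(
    list(log_a_mean = 0, log_a_sd = 0.5, b_mean = 0, b_sd = 2), priors)

  set.seed(seed)
  # init: difficulty from observed proportion correct, abilities from totals
  pbar <- pmin(pmax(colSums(y0) / pmax(colSums(mask), 1), 0.05), 0.95)
  sample_items <- is.null(fix_items)
  a <- if (sample_items) rep(1, J) else rep(fix_items$a, length.out = J)
  b <- if (sample_items) stats::qlogis(1 - pbar) else rep(fix_items$b, length.out = J)
  prop_i <- rowSums(y0) / pmax(rowSums(mask), 1)
  th_g <- as.numeric(scale(stats::qlogis(pmin(pmax(prop_i, 0.05), 0.95))))
  if (any(!is.finite(th_g))) th_g <- rep(0, n)
  th_d <- matrix(rep(th_g, D), n, D)
  lam <- rep(0.6, D)

  step <- list(a = 0.2, b = 0.3, th = rep(0.6, D), lam = 0.1)
  acc <- list(a = 0, b = 0, th = rep(0, D), lam = rep(0, D))
  try_n <- 0L

  keep <- seq(n_burn + 1L, n_iter, by = thin)
  R <- length(keep)
  ch_a <- if (store_chains) matrix(NA_real_, R, J) else NULL
  ch_b <- if (store_chains) matrix(NA_real_, R, J) else NULL
  ch_lam <- if (store_chains) matrix(NA_real_, R, D) else NULL
  ch_tg <- if (store_chains) matrix(NA_real_, R, n) else NULL
  ch_td <- if (store_chains) lapply(seq_len(D), function(d) matrix(NA_real_, R, n)) else NULL
  sum_a <- numeric(J); sum_b <- numeric(J); sum_lam <- numeric(D)
  sum_tg <- numeric(n); sum_td <- matrix(0, n, D)
  kept <- 0L

  dom_cols <- lapply(seq_len(D), function(d) which(dom == d))
  one_n <- rep(1, n)

  # row log-likelihood of a candidate theta vector on a subset of items
  ll_rows <- function(th, cols) {
    aj <- a[cols]; abj <- aj * b[cols]
    eta <- cbind(th, one_n) %*% rbind(aj, -abj)
    rowSums(ll_cells(eta, y0[, cols, drop = FALSE], mask[, cols, drop = FALSE]))
  }
  # column log-likelihood for candidate item parameter vectors
  ll_cols <- function(a_c, b_c) {
    Th_t <- t(th_d[, dom, drop = FALSE])       # J x n
    eta_t <- Th_t * a_c - a_c * b_c            # recycles along rows (items)
    rowSums(ll_cells(eta_t, t(y0), t(mask)))
  }

  for (it in seq_len(n_iter)) {
    adapting <- it <= n_burn
    try_n <- try_n + 1L

    # -- domain abilities (random-walk MH, vectorized over patients) -------
    sdd <- sqrt(1 - lam^2)
    for (d in seq_len(D)) {
      cur <- th_d[, d]
      cand <- cur + step$th[d] * stats::rnorm(n)
      lp_cur <- ll_rows(cur, dom_cols[[d]]) +
        stats::dnorm(cur, lam[d] * th_g, sdd[d], log = TRUE)
      lp_new <- ll_rows(cand, dom_cols[[d]]) +
        stats::dnorm(cand, lam[d] * th_g, sdd[d], log = TRUE)
      ok <- log(stats::runif(n)) < (lp_new - lp_cur)
      th_d[ok, d] <- cand[ok]
      acc$th[d] <- acc$th[d] + mean(ok)
    }

    # -- general ability (exact normal full conditional) -------------------
    w <- lam^2 / (1 - lam^2)
    prec <- 1 + sum(w)
    mu <- (th_d %*% (lam / (1 - lam^2))) / prec
    th_g <- stats::rnorm(n, mu, sqrt(1 / prec))

    # -- item parameters ---------------------------------------------------
    if (sample_items) {
      la <- log(a)
      la_new <- la + step$a * stats::rnorm(J)
      ll_old <- ll_cols(a, b)
      ll_new <- {
        a_try <- exp(la_new)
        Th_t <- t(th_d[, dom, drop = FALSE])
        eta_t <- Th_t * a_try - a_try * b
        rowSums(ll_cells(eta_t, t(y0), t(mask)))
      }
      lp_old <- ll_old + stats::dnorm(la, pr$log_a_mean, pr$log_a_sd, log = TRUE)
      lp_new <- ll_new + stats::dnorm(la_new, pr$log_a_mean, pr$log_a_sd, log = TRUE)
      ok <- log(stats::runif(J)) < (lp_new - lp_old)
      a[ok] <- exp(la_new[ok])
      acc$a <- acc$a + mean(ok)

      b_new <- b + step$b * stats::rnorm(J)
      ll_old <- ll_cols(a, b)
      ll_new <- ll_cols(a, b_new)
      lp_old <- ll_old + stats::dnorm(b, pr$b_mean, pr$b_sd, log = TRUE)
      lp_new <- ll_new + stats::dnorm(b_new, pr$b_mean, pr$b_sd, log = TRUE)
      ok <- log(stats::runif(J)) < (lp_new - lp_old)
      b[ok] <- b_new[ok]
      acc$b <- acc$b + mean(ok)
    }

    # -- loadings (random-walk MH on (0,1), uniform prior) -----------------
    for (d in seq_len(D)) {
      cand <- lam[d] + step$lam * stats::rnorm(1)
      if (cand > 0 && cand < 1) {
        lp_cur <- sum(stats::dnorm(th_d[, d], lam[d] * th_g,
                                   sqrt(1 - lam[d]^2), log = TRUE))
        lp_new <- sum(stats::dnorm(th_d[, d], cand * th_g,
                                   sqrt(1 - cand^2), log = TRUE))
        if (log(stats::runif(1)) < lp_new - lp_cur) {
          lam[d] <- cand
          acc$lam[d] <- acc$lam[d] + 1
        }
      }
    }

    # -- step-size adaptation during burn-in -------------------------------
    if (adapting && it %% 50L == 0L) {
      tune <- function(s, rate) {
        if (rate > 0.5) s * 1.25 else if (rate < 0.2) s * 0.75 else s
      }
      step$a <- tune(step$a, acc$a / try_n)
      step$b <- tune(step$b, acc$b / try_n)
      for (d in seq_len(D)) step$th[d] <- tune(step$th[d], acc$th[d] / try_n)
      step$lam <- tune(step$lam, mean(acc$lam) / try_n)
      acc <- list(a = 0, b = 0, th = rep(0, D), lam = rep(0, D))
      try_n <- 0L
    }

    # -- retain ------------------------------------------------------------
    if (it > n_burn && (it - n_burn - 1L) %% thin == 0L) {
      kept <- kept + 1L
      if (store_chains) {
        ch_a[kept, ] <- a; ch_b[kept, ] <- b; ch_lam[kept, ] <- lam
        ch_tg[kept, ] <- th_g
        for (d in seq_len(D)) ch_td[[d]][kept, ] <- th_d[, d]
      }
      sum_a <- sum_a + a; sum_b <- sum_b + b; sum_lam <- sum_lam + lam
      sum_tg <- sum_tg + th_g; sum_td <- sum_td + th_d
    }
  }

  acc_rates <- list(a = acc$a / max(try_n, 1), b = acc$b / max(try_n, 1),
                    theta = acc$th / max(try_n, 1),
                    lambda = acc$lam / max(try_n, 1))
  out <- list(
    items = data.frame(a = sum_a / kept, b = sum_b / kept,
                       domain = dom_f),
    lambda = stats::setNames(sum_lam / kept, levels(dom_f)),
    theta_g = sum_tg / kept,
    theta_d = {
      td <- sum_td / kept; colnames(td) <- levels(dom_f); td
    },
    chains = if (store_chains)
      list(a = ch_a, b = ch_b, lambda = ch_lam, theta_g = ch_tg,
           theta_d = ch_td) else NULL,
    n_retained = kept,
    config = list(n_iter = n_iter, n_burn = n_burn, thin = thin, seed = seed,
                  priors = pr, domains = levels(dom_f),
                  items_sampled = sample_items),
    acceptance = acc_rates,
    n = n, J = J,
    responses = y,
    call = match.call())
  class(out) <- "hoirt"
  out
}

#' Expected a posteriori (EAP) ability scores
#'
#' Posterior-mean latent scores per patient: the overall (general-factor)
#' score and one score per content domain, i.e. SSHO2D/dccs2D/psm2D for the
#' two-domain model over DCCS and PSM, and SSHO/dccs/psm/arw/mfs/nsm for the
#' five-domain model. EAPs are arithmetic means over the retained MCMC draws.
#'
#' @param fit a fitted \code{\link{hoirt}} model.
#' @return A data frame with one row per patient. For a two-domain fit the
#'   columns are \code{ssho2d}, \code{d2_<domain>}; for a five-domain fit
#'   \code{ssho}, \code{d5_<domain>}; otherwise \code{theta_g},
#'   \code{theta_<domain>}.
#' @export
eap_scores <- function(fit) {
  stopifnot(inherits(fit, "hoirt"))
  D <- length(fit$lambda)
  doms <- tolower(fit$config$domains)
  out <- data.frame(fit$theta_g, fit$theta_d)
  names(out) <- if (D == 2L) c("ssho2d", paste0("d2_", doms))
    else if (D == 5L) c("ssho", paste0("d5_", doms))
    else c("theta_g", paste0("theta_", doms))
  out
}
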