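test_that("the 2PL response function behaves like a logistic in theta", {
  expect_equal(irf_2pl(1, 0, 0), 0.5)
  expect_equal(irf_2pl(1.5, 1, 1), 0.5)
  expect_equal(irf_2pl(2, 0, 1), 1 / (1 + exp(-2)))
  expect_error(irf_2pl(-1, 0, 0), "a must be")
  th <- seq(-4, 4, by = 0.25)
  p <- irf_2pl(1.3, 0.4, th)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("the observed-data log-likelihood sums Bernoulli terms over observed cells", {
  items <- data.frame(a = 1, b = 0, domain = 1L)
  # one patient, one correct response at theta = 0: log 0.5
  expect_equal(
    response_loglik(matrix(1, 1, 1), items, lambda = 0.7,
                    theta_g = 0, theta_d = matrix(0, 1, 1)),
    log(0.5))
  # all cells missing: empty sum
  expect_equal(
    response_loglik(matrix(NA, 2, 1), items, lambda = 0.7,
                    theta_g = c(0, 1), theta_d = matrix(0, 2, 1)),
    0)
  # flipping a correct response to incorrect when irf > 0.5 lowers the value
  set.seed(3)
  items <- data.frame(a = runif(6, 0.8, 2), b = runif(6, -1, 0),
                      domain = rep(1:2, each = 3))
  y <- matrix(1, 2, 6)
  td <- matrix(1, 2, 2)          # irf(theta = 1 > b) > 0.5 for all items
  ll1 <- response_loglik(y, items, c(0.7, 0.8), c(1, 1), td)
  y[1, 4] <- 0
  ll2 <- response_loglik(y, items, c(0.7, 0.8), c(1, 1), td)
  expect_lt(ll2, ll1)
})

test_that("the generator respects the higher-order structure", {
  items <- data.frame(a = rep(1, 10), b = rep(0, 10), domain = rep(1:2, 5))
  s1 <- simulate_hoirt(items, c(0.7, 0.8), 50, seed = 4)
  s2 <- simulate_hoirt(items, c(0.7, 0.8), 50, seed = 4)
  expect_identical(s1, s2)                       # determinism
  s3 <- simulate_hoirt(items, c(1, 1), 200, seed = 5)
  expect_equal(cor(s3$theta_g, s3$theta_d[, 1]), 1)   # degenerate loading
  expect_equal(cor(s3$theta_g, s3$theta_d[, 2]), 1)
  # unit marginal variance of domain abilities (large n)
  s4 <- simulate_hoirt(items, c(0.6, 0.9), 20000, seed = 6)
  expect_equal(apply(s4$theta_d, 2, sd), c(1, 1), tolerance = 0.03)
})

test_that("near-zero discrimination yields coin-flip items", {
  items <- data.frame(a = rep(1e-6, 5), b = runif(5, -2, 2),
                      domain = rep(1L, 5))
  s <- simulate_hoirt(items, 0.7, 10000, seed = 7)
  expect_equal(unname(colMeans(s$responses)), rep(0.5, 5), tolerance = 0.02)
})

test_that("the MCMC chain is reproducible and EAPs equal stored-draw means", {
  items <- data.frame(a = runif(16, 0.8, 1.8), b = rnorm(16),
                      domain = rep(1:2, each = 8))
  sim <- simulate_hoirt(items, c(0.7, 0.8), 40, seed = 8)
  f1 <- hoirt(sim$responses, items$domain, n_iter = 400, n_burn = 150,
              seed = 9)
  f2 <- hoirt(sim$responses, items$domain, n_iter = 400, n_burn = 150,
              seed = 9)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$theta_g, f2$theta_g)
  expect_equal(f1$n_retained, 250)
  # EAP = arithmetic mean of retained draws, recomputed independently
  expect_equal(f1$theta_g, colMeans(f1$chains$theta_g), tolerance = 1e-12)
  expect_equal(f1$items$a, colMeans(f1$chains$a), tolerance = 1e-12)
  expect_equal(unname(f1$lambda), colMeans(f1$chains$lambda),
               tolerance = 1e-12)
  # thinning changes the retained count as floor((n_iter - n_burn)/thin)
  f3 <- hoirt(sim$responses, items$domain, n_iter = 400, n_burn = 150,
              thin = 3, seed = 9)
  expect_equal(f3$n_retained, length(seq(151, 400, by = 3)))
})

test_that("uninformative items leave the ability posterior at its prior", {
  set.seed(10)
  y <- matrix(rbinom(30 * 6, 1, 0.5), 30, 6)
  fit <- hoirt(y, rep(1:2, each = 3), n_iter = 5000, n_burn = 1000,
               seed = 11, fix_items = list(a = rep(1e-6, 6), b = rep(0, 6)))
  # every EAP stays near the prior mean up to Monte Carlo error, and the
  # patient-average sits tight at zero
  expect_true(all(abs(fit$theta_g) < 0.15))
  expect_lt(abs(mean(fit$theta_g)), 0.05)
})

test_that("observed successes tilt the ability posterior upward", {
  # single patient answering two easy-ish fixed items correctly
  y <- matrix(c(1L, 1L), 1, 2)
  fit <- hoirt(y, c(1L, 1L), n_iter = 2000, n_burn = 500, seed = 12,
               fix_items = list(a = c(1, 1), b = c(0, 0)))
  expect_gt(fit$theta_g, 0)
})

test_that("degenerate inputs are rejected with the offending domain named", {
  y <- matrix(c(1L, 0L, NA, NA), 2, 2)
  expect_error(hoirt(y, factor(c("DCCS", "PSM")), n_iter = 10, n_burn = 2),
               "fewer than 2 items")
  y <- cbind(matrix(rbinom(8, 1, 0.5), 4, 2),
             matrix(NA_integer_, 4, 2))
  expect_error(hoirt(y, rep(c("DCCS", "MFS"), each = 2), n_iter = 10,
                     n_burn = 2), "MFS")
  expect_error(hoirt(matrix(NA_integer_, 2, 4), rep(1:2, 2),
                     n_iter = 10, n_burn = 2), "at least one observed")
})

test_that("moderate-size fits recover the generating structure", {
  set.seed(13)
  items <- data.frame(a = runif(24, 0.8, 2), b = runif(24, -1.5, 1.5),
                      domain = rep(1:2, each = 12))
  sim <- simulate_hoirt(items, c(0.7, 0.8), 200, seed = 13)
  fit <- hoirt(sim$responses, items$domain, n_iter = 1500, n_burn = 600,
               seed = 14, store_chains = FALSE)
  expect_gt(cor(sim$theta_g, fit$theta_g), 0.6)
  expect_gt(cor(sim$theta_d[, 1], fit$theta_d[, 1]), 0.75)
  expect_gt(cor(items$a, fit$items$a), 0.6)
  expect_gt(cor(items$b, fit$items$b), 0.9)
  # removing a patient's data pulls the EAP back toward the prior mean
  y2 <- sim$responses
  y2[1:20, ] <- NA
  y2[1:20, 1] <- sim$responses[1:20, 1]    # keep one observed response
  fit2 <- hoirt(y2, items$domain, n_iter = 1500, n_burn = 600, seed = 14,
                store_chains = FALSE)
  shrunk <- abs(fit2$theta_g[1:20]) < abs(fit$theta_g[1:20])
  expect_gte(mean(shrunk), 0.75)
})

test_that("hoirt methods expose the fitted model coherently", {
  items <- data.frame(a = runif(12, 0.8, 1.8), b = rnorm(12),
                      domain = rep(1:2, each = 6))
  sim <- simulate_hoirt(items, c(0.7, 0.8), 30, seed = 15)
  fit <- hoirt(sim$responses, factor(rep(c("DCCS", "PSM"), each = 6)),
               n_iter = 400, n_burn = 150, seed = 16)
  sc <- eap_scores(fit)
  expect_named(sc, c("ssho2d", "d2_dccs", "d2_psm"))
  expect_true(all(is.finite(unlist(sc))))
  expect_equal(predict(fit), sc)
  pm <- predict(fit, type = "prob")
  expect_equal(dim(pm), c(30, 12))
  expect_true(all(pm > 0 & pm < 1))
  expect_length(coef(fit), 2 * 12 + 2)
  r <- residuals(fit)
  expect_equal(dim(r), c(30, 12))
  expect_true(all(abs(r[!is.na(r)]) < 1))
  s <- summary(fit)
  expect_s3_class(s, "summary.hoirt")
  expect_lt(max(s$split_lambda), 0.5)
  sims <- simulate(fit, nsim = 2, seed = 17)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]$responses), c(30, 12))
})
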