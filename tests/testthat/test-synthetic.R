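test_that("the default item bank matches the battery layout", {
  bank <- generate_default_item_bank(seed = 1)
  expect_equal(nrow(bank$items), 266)
  expect_equal(as.vector(table(bank$items$domain)[instrument_names()]),
               c(30, 12, 50, 30, 144))
  expect_true(all(bank$items$a > 0))
  expect_true(all(bank$lambda > 0.5 - 1e-9 & bank$lambda < 0.9 + 1e-9))
  expect_identical(bank, generate_default_item_bank(seed = 1))
})

test_that("generated cohorts carry the configured epidemiology", {
  g <- generate_cohort(cohort_sim_config(n = 86, seed = 2))
  n_imp <- sum(g$cohort$patients$impaired)
  expect_gte(n_imp, 12)         # central 99% binomial range around 19
  expect_lte(n_imp, 27)
  expect_true(all(g$cohort$patients$age >= 67 &
                    g$cohort$patients$age <= 93))
  g2 <- generate_cohort(cohort_sim_config(n = 86, seed = 2))
  expect_identical(g2$cohort$responses, g$cohort$responses)
  expect_identical(g2$latents, g$latents)
})

test_that("large-sample moments match their targets", {
  g <- generate_cohort(cohort_sim_config(n = 1000, seed = 3))
  sc <- classical_scores(g$cohort)
  expect_lt(abs(mean(sc$rt_dccs) - 36.049) / 36.049, 0.2)
  expect_lt(abs(mean(sc$rt_arw) - 47.421) / 47.421, 0.2)
  expect_lt(abs(mean(sc$rt_psm) - 73) / 73, 0.2)
  # age-impairment association near the configured 0.27
  r <- cor(g$cohort$patients$age, g$cohort$patients$impaired)
  expect_lt(abs(r - 0.27), 0.1)
  g5 <- generate_cohort(cohort_sim_config(n = 5000, seed = 4))
  expect_lt(abs(mean(g5$latents$theta_g)), 0.1)
})

test_that("MFS/NSM missingness ramps monotonically along the item index", {
  g <- generate_cohort(cohort_sim_config(n = 400, seed = 5))
  for (nm in c("MFS", "NSM")) {
    rate <- colMeans(is.na(g$cohort$responses[[nm]]))
    expect_true(all(diff(rate) >= 0))
    expect_equal(rate[[1]], 0)
  }
  expect_false(anyNA(g$cohort$responses$DCCS))
  expect_false(anyNA(g$cohort$responses$ARW))
})

test_that("the ability gap controls the impairment signal", {
  auc_at <- function(gap) {
    g <- generate_cohort(cohort_sim_config(n = 2000, ability_gap = gap,
                                           seed = 6))
    auc_score(-g$latents$theta_g, g$cohort$patients$impaired)
  }
  a0 <- auc_at(0); a1 <- auc_at(1); a2 <- auc_at(2)
  expect_lt(abs(a0 - 0.5), 0.08)        # no-signal null
  expect_gt(a1, a0)
  expect_gt(a2, a1)
  expect_gt(a2, 0.85)
})

test_that("the end-to-end benchmark fixture feeds every feature space", {
  fx <- make_benchmark_fixture(cohort_sim_config(n = 300, ability_gap = 2,
                                                 seed = 7),
                               n_iter = 400, n_burn = 150)
  expect_equal(vapply(fx$features, ncol, 0L),
               lengths(feature_spaces()))
  expect_false(anyNA(fx$features$F15))
  expect_true(all(fx$bundle$composite4 > 0 & fx$bundle$composite4 < 1))
  # strong ability gap: the fitted 2D overall score separates the groups
  y <- fx$cohort$patients$impaired
  expect_gte(auc_score(-fx$bundle$ssho2d, y), 0.82)
  # and a classifier on {age, ssho2d} carries that signal to held-out data
  sp <- split_cohort(y, 0.8, seed = 8)
  fit <- grid_search_train("RF", fx$features$F15[sp$train, ], y[sp$train],
                           seed = 9)
  pr <- predict(fit, fx$features$F15[sp$test, ])
  expect_gte(auc_score(pr$scores, y[sp$test]), 0.75)
})
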