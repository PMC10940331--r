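test_that("the feature-space registry matches the documented layout", {
  fs <- feature_spaces()
  expect_equal(names(fs), paste0("F", 1:16))
  expect_equal(lengths(fs)[c("F1", "F2", "F3", "F4", "F7", "F8", "F11",
                             "F15", "F16")],
               c(F1 = 13L, F2 = 9L, F3 = 10L, F4 = 6L, F7 = 3L, F8 = 1L,
                 F11 = 2L, F15 = 2L, F16 = 5L))
  expect_equal(fs$F15, c("age", "ssho2d"))
  expect_equal(fs$F8, "composite1")
})

test_that("feature matrices encode demographics and keep registry order", {
  fx <- load_printed_fixture()
  m <- build_feature_matrix(fx, "F15")
  expect_equal(colnames(m), c("age", "ssho2d"))
  expect_equal(m[, "age"], fx$age)
  expect_error(build_feature_matrix(fx, "F1"), "F1")   # names the space
  cb <- data.frame(gender = c("F", "M"), race = c("W", "A"),
                   income = c("D", "2"), education = c("9", "777"))
  enc <- build_feature_matrix(cb, c("gender", "race", "income", "education"))
  expect_equal(enc[, "gender"], c(0, 1))
  expect_equal(enc[, "race"], c(3, 0))
  expect_equal(enc[, "income"], c(8, 0))
  expect_equal(enc[, "education"], c(9, 777))
})

test_that("stratified splitting reproduces the 68/18 protocol and is seeded", {
  lab <- rep(c(0L, 1L), c(67, 19))
  sp <- split_cohort(lab, 0.8, seed = 1)
  expect_length(sp$train, 68)
  expect_length(sp$test, 18)
  expect_equal(sum(lab[sp$test]), 4)       # 19 * 18/86 rounded by remainder
  expect_setequal(c(sp$train, sp$test), 1:86)
  expect_identical(sp, split_cohort(lab, 0.8, seed = 1))
  expect_false(identical(sp$test, split_cohort(lab, 0.8, seed = 2)$test))
  expect_length(split_cohort(rep(0:1, 5), 0.8, seed = 3)$train, 8)
  expect_error(split_cohort(c(0, 0, 0, 1), 0.8, seed = 1), "absent")
})

test_that("grid search is deterministic and a one-point grid is a plain fit", {
  set.seed(51)
  x <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("p", "q")))
  y <- as.integer(x[, 1] + rnorm(60, 0, 0.5) > 0)
  spec <- model_spec("RF")
  spec$grid <- spec$grid[3, , drop = FALSE]    # one-point grid
  f1 <- grid_search_train(spec, x, y, seed = 4)
  expect_equal(f1$best_params$ntree, spec$grid$ntree[1])
  f2 <- grid_search_train(model_spec("RF"), x, y, seed = 4)
  f3 <- grid_search_train(model_spec("RF"), x, y, seed = 4)
  expect_identical(f2$best_params, f3$best_params)
  expect_identical(predict(f2, x)$labels, predict(f3, x)$labels)
  expect_error(grid_search_train("RF", x, rep(1L, 60)), "single class")
})

test_that("every model in the zoo separates well-separated Gaussians", {
  set.seed(52)
  n <- 200
  y <- rep(0:1, each = n / 2)
  x <- cbind(a = rnorm(n, y * 6), b = rnorm(n, -y * 6))
  sp <- split_cohort(y, 0.8, seed = 5)
  for (mod in c("SVC", "LRG", "Tree", "KNN", "RF", "GB", "ANN")) {
    fit <- grid_search_train(mod, x[sp$train, ], y[sp$train], seed = 6)
    pr <- predict(fit, x[sp$test, ])
    expect_gte(mean(pr$labels == y[sp$test]), 0.95)
    expect_gte(auc_score(pr$scores, y[sp$test]), 0.95)
  }
})

test_that("a perfect stub classifier bootstraps to mean 1 and sd 0", {
  stub <- structure(list(
    name = "stub",
    grid = data.frame(dummy = 1),
    fit = function(x, y, p) NULL,
    predict = function(m, x) list(labels = as.integer(x[, 1]),
                                  scores = x[, 1])),
    class = "model_spec")
  y <- rep(c(0L, 1L), c(30, 12))
  x <- cbind(truth = y)
  bs <- bootstrap_evaluate(x, y, stub, B = 20, seed = 7)
  for (m in c("precision", "recall", "accuracy", "specificity", "f_score",
              "qwk", "auc")) {
    expect_equal(unname(bs$mean[m]), 1)
    expect_equal(unname(bs$sd[m]), 0)
  }
})

test_that("a single bootstrap replication equals the direct train/evaluate run", {
  fx <- load_printed_fixture()
  x <- build_feature_matrix(fx, "F15")
  y <- fx$impaired
  bs <- bootstrap_evaluate(x, y, "RF", B = 1, seed = 9)
  # replay the replication's seeds by hand
  set.seed(9)
  rs <- sample.int(2^30, 1)
  set.seed(rs)
  idx <- sample.int(86, 86, replace = TRUE)
  sp <- split_cohort(y[idx], 0.8, seed = rs + 1L)
  fit <- grid_search_train("RF", x[idx[sp$train], ], y[idx[sp$train]],
                           seed = rs + 2L)
  pr <- predict(fit, x[idx[sp$test], ])
  ev <- evaluate(pr$labels, y[idx[sp$test]], scores = pr$scores)
  expect_equal(unname(bs$draws[1, "accuracy"]), ev$accuracy)
  expect_equal(unname(bs$draws[1, "auc"]), ev$auc)
})

test_that("kmeans inertia is non-increasing in k with closed-form endpoints", {
  set.seed(53)
  x <- matrix(rnorm(60 * 3), 60, 3)
  el <- kmeans_elbow(x, k_max = 10, seed = 1)
  expect_true(all(diff(el$inertia) <= 1e-8))
  # k = 1: total squared deviation from the grand mean
  expect_equal(unname(el$inertia[1]),
               sum(scale(x, scale = FALSE)^2), tolerance = 1e-8)
  expect_length(el$labels, 60)
  expect_equal(sort(unique(el$labels)), 1:3)
  # k = n puts every point in its own cluster
  xs <- matrix(rnorm(24), 12, 2)
  expect_equal(unname(kmeans_elbow(xs, k_max = 12, seed = 2,
                                   k_select = 2)$inertia[12]), 0)
  # monotone over many random datasets
  for (s in 1:20) {
    set.seed(s)
    xr <- matrix(rnorm(40 * 2), 40, 2)
    expect_true(all(diff(kmeans_elbow(xr, k_max = 10, seed = s)$inertia)
                    <= 1e-8))
  }
})
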