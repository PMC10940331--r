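#' Classifier zoo specifications
#'
#' Each model comes with the hyperparameter grid the benchmark searches:
#' \describe{
#'   \item{SVC}{radial-kernel support vector classifier, cost C in
#'     \{1, 10, 50, 100\} (e1071).}
#'   \item{LRG}{L2-penalized logistic regression, 20 log-spaced strengths
#'     C in [0.01, 5] (glmnet ridge).}
#'   \item{Tree}{decision tree, 7 max-depth values spanning 3..30 (rpart).}
#'   \item{KNN}{k-nearest neighbours, k in \{3, 5, 7, 9\} (class).}
#'   \item{RF}{random forest, 10 tree counts spanning 10..500
#'     (randomForest).}
#'   \item{GB}{gradient boosting, tree counts \{10, 30, 50\} (xgboost).}
#'   \item{ANN}{single-hidden-layer perceptron, size \{150, 120\} x decay
#'     \{0.01, 0.3, 1\}, inputs standardized internally (nnet).}
#' }
#'
#' @param name model name.
#' @return An object of class \code{model_spec} with fields \code{name},
#'   \code{grid} (data frame of candidate hyperparameters), \code{fit} and
#'   \code{predict} functions.
#' @export
model_spec <- function(name = c("SVC", "LRG", "Tree", "KNN", "RF", "GB",
                                "ANN")) {
  name <- match.arg(name)
  spec <- switch(name,
    SVC = list(
      grid = data.frame(C = c(1, 10, 50, 100)),
      fit = function(x, y, p) {
        e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                   cost = p$C, probability = TRUE)
      },
      predict = function(m, x) {
        pr <- stats::predict(m, x, probability = TRUE)
        list(labels = as.integer(as.character(pr)),
             scores = attr(pr, "probabilities")[, "1"])
      }),
    LRG = list(
      grid = data.frame(C = exp(seq(log(0.01), log(5), length.out = 20))),
      fit = function(x, y, p) {
        xx <- if (ncol(x) < 2L) cbind(x, .ridge_pad = 0) else x
        m <- glmnet::glmnet(xx, factor(y, levels = c(0, 1)),
                            family = "binomial", alpha = 0,
                            lambda = 1 / (nrow(xx) * p$C))
        list(fit = m, pad = ncol(x) < 2L)
      },
      predict = function(m, x) {
        xx <- if (m$pad) cbind(x, .ridge_pad = 0) else x
        s <- as.numeric(stats::predict(m$fit, xx, type = "response"))
        list(labels = as.integer(s > 0.5), scores = s)
      }),
    Tree = list(
      grid = data.frame(maxdepth = unique(round(seq(3, 30, length.out = 7)))),
      fit = function(x, y, p) {
        d <- data.frame(.y = factor(y, levels = c(0, 1)), x)
        rpart::rpart(.y ~ ., d, method = "class",
                     control = rpart::rpart.control(maxdepth = p$maxdepth,
                                                    cp = 0, minsplit = 2,
                                                    xval = 0))
      },
      predict = function(m, x) {
        s <- stats::predict(m, data.frame(x), type = "prob")[, "1"]
        list(labels = as.integer(s > 0.5), scores = s)
      }),
    KNN = list(
      grid = data.frame(k = c(3, 5, 7, 9)),
      fit = function(x, y, p) list(x = x, y = factor(y, levels = c(0, 1)),
                                   k = p$k),
      predict = function(m, x) {
        pr <- class::knn(m$x, x, m$y, k = m$k, prob = TRUE)
        pwin <- attr(pr, "prob")
        lab <- as.integer(as.character(pr))
        list(labels = lab, scores = ifelse(lab == 1, pwin, 1 - pwin))
      }),
    RF = list(
      grid = data.frame(ntree = round(seq(10, 500, length.out = 10))),
      fit = function(x, y, p) {
        randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                   ntree = p$ntree)
      },
      predict = function(m, x) {
        s <- stats::predict(m, x, type = "prob")[, "1"]
        list(labels = as.integer(s > 0.5), scores = s)
      }),
    GB = list(
      grid = data.frame(nrounds = c(10, 30, 50)),
      fit = function(x, y, p) {
        xgboost::xgboost(x, factor(y, levels = c(0, 1)),
                         nrounds = p$nrounds, max_depth = 3,
                         learning_rate = 0.1, nthreads = 1, verbosity = 0)
      },
      predict = function(m, x) {
        s <- as.numeric(stats::predict(m, x, type = "response"))
        list(labels = as.integer(s > 0.5), scores = s)
      }),
    ANN = list(
      grid = expand.grid(size = c(150, 120), decay = c(0.01, 0.3, 1)),
      fit = function(x, y, p) {
        mu <- colMeans(x)
        sdv <- apply(x, 2, stats::sd); sdv[sdv == 0] <- 1
        xs <- scale(x, mu, sdv)
        d <- data.frame(.y = factor(y, levels = c(0, 1)), xs)
        m <- nnet::nnet(.y ~ ., d, size = p$size, decay = p$decay,
                        maxit = 200, trace = FALSE, MaxNWts = 100000)
        list(fit = m, mu = mu, sd = sdv)
      },
      predict = function(m, x) {
        xs <- scale(x, m$mu, m$sd)
        s <- as.numeric(stats::predict(m$fit, data.frame(xs), type = "raw"))
        list(labels = as.integer(s > 0.5), scores = s)
      }))
  structure(c(list(name = name), spec), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec", x$name, "- grid of", nrow(x$grid), "candidate(s):\n")
  print(x$grid, row.names = FALSE)
  invisible(x)
}

stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    ix <- which(y == cl)
    f[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  f
}

#' Grid-search training with stratified cross-validation
#'
#' Evaluates every point of the model's hyperparameter grid by stratified
#' k-fold cross-validation on the training data, selects the grid point with
#' the best mean validation accuracy (ties broken by grid order), and refits
#' it on the full training set.
#'
#' @param spec a \code{\link{model_spec}} (or model name).
#' @param x numeric training matrix.
#' @param y 0/1 training labels (both classes required).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed; identical seed, data and spec give identical
#'   chosen hyperparameters and fitted model.
#' @return An object of class \code{grid_fit} with fields \code{model},
#'   \code{best_params}, \code{cv} (grid with mean CV accuracy) and
#'   \code{spec}.
#' @export
grid_search_train <- function(spec, x, y, folds = 5L, seed = 1L) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("training data contain a single class")
  if (nrow(x) < folds) stop("fewer training rows than folds")
  set.seed(seed)
  fold_id <- stratified_folds(y, folds)
  G <- nrow(spec$grid)
  cv_acc <- numeric(G)
  for (g in seq_len(G)) {
    p <- spec$grid[g, , drop = FALSE]
    accs <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      if (length(unique(y[tr])) < 2L) { accs[k] <- NA; next }
      set.seed((seed + 7919L * g + 104729L * k) %% .Machine$integer.max)
      m <- spec$fit(x[tr, , drop = FALSE], y[tr], p)
      pr <- spec$predict(m, x[!tr, , drop = FALSE])
      accs[k] <- mean(pr$labels == y[!tr])
    }
    cv_acc[g] <- mean(accs, na.rm = TRUE)
  }
  best <- which.max(cv_acc)     # first maximum = grid-order tie-break
  set.seed((seed + 31L) %% .Machine$integer.max)
  model <- spec$fit(x, y, spec$grid[best, , drop = FALSE])
  structure(list(model = model, spec = spec,
                 best_params = as.list(spec$grid[best, , drop = FALSE]),
                 cv = cbind(spec$grid, mean_cv_accuracy = cv_acc),
                 features = colnames(x)),
            class = "grid_fit")
}

#' @export
predict.grid_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$features
  object$spec$predict(object$model, newdata)
}

#' @export
print.grid_fit <- function(x, ...) {
  cat("Grid-search fit:", x$spec$name, "\n  chosen:",
      paste(names(x$best_params), unlist(x$best_params), sep = "=",
            collapse = ", "),
      sprintf("(mean CV accuracy %.3f)\n",
              max(x$cv$mean_cv_accuracy)))
  invisible(x)
}
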