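#' Model adapters: a uniform contract over underlying learners
#'
#' Conformal prediction is model-agnostic; the package talks to any learner
#' through a `model_adapter`: a training function plus a class-probability
#' predictor (classification) or a point predictor (regression). Probability
#' vectors are non-negative and sum to one; training twice with the same data
#' and seed yields identical predictions (all shipped adapters route their
#' randomness through the seed passed to [adapter_fit()]).
#'
#' @param name adapter name (used in logs and reports).
#' @param task `"classification"` or `"regression"`.
#' @param fit `function(x, y)` returning a fitted model object; called inside
#'   a seeded RNG scope.
#' @param predict_prob `function(model, x, label_space)` returning an
#'   `n x K` probability matrix with columns in `label_space` order
#'   (classification adapters).
#' @param predict_point `function(model, x)` returning numeric predictions
#'   (regression adapters).
#' @param params named list of hyperparameters (recorded in reports).
#' @return an object of class `model_adapter`.
#' @export
model_adapter <- function(name, task, fit, predict_prob = NULL,
                          predict_point = NULL, params = list()) {
  task <- match.arg(task, c("classification", "regression"))
  if (task == "classification" && is.null(predict_prob)) {
    stopf("classification adapter needs `predict_prob`")
  }
  if (task == "regression" && is.null(predict_point)) {
    stopf("regression adapter needs `predict_point`")
  }
  structure(
    list(name = name, task = task, fit = fit, predict_prob = predict_prob,
         predict_point = predict_point, params = params),
    class = "model_adapter"
  )
}

#' @export
print.model_adapter <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(sprintf("%s=%s", names(x$params), vapply(x$params, format, "")),
          collapse = ", ")
  } else "defaults"
  cat(sprintf("<model_adapter> %s (%s; %s)\n", x$name, x$task, ps))
  invisible(x)
}

#' Fit an adapter on a feature matrix
#'
#' @param adapter a [model_adapter()].
#' @param x numeric feature matrix.
#' @param y labels: character/factor (classification) or numeric (regression).
#' @param seed integer seed controlling any training randomness.
#' @param label_space explicit label order; defaults to the sorted unique
#'   labels.
#' @return an object of class `fitted_adapter`.
#' @export
adapter_fit <- function(adapter, x, y, seed = 1L, label_space = NULL) {
  if (!inherits(adapter, "model_adapter")) stopf("`adapter` must be a model_adapter")
  x <- as.matrix(x)
  if (adapter$task == "classification") {
    y <- as.character(y)
    label_space <- label_space %||% sort(unique(y))
  } else {
    y <- as.numeric(y)
    label_space <- NULL
  }
  model <- with_seed(seed, adapter$fit(x, y))
  structure(
    list(adapter = adapter, model = model, label_space = label_space,
         task = adapter$task, seed = as.integer(seed),
         n_train = nrow(x), feature_ids = colnames(x)),
    class = "fitted_adapter"
  )
}

#' Predict class probabilities from a fitted adapter
#'
#' @param fitted a `fitted_adapter` from [adapter_fit()].
#' @param x feature matrix.
#' @return `n x K` probability matrix, columns named by the label space.
#' @export
predict_prob <- function(fitted, x) {
  if (fitted$task != "classification") stopf("probability predictions need a classification adapter")
  x <- as.matrix(x)
  pr <- fitted$adapter$predict_prob(fitted$model, x, fitted$label_space)
  pr <- as.matrix(pr)
  if (ncol(pr) != length(fitted$label_space)) stopf("adapter returned a malformed probability matrix")
  colnames(pr) <- fitted$label_space
  bad <- abs(rowSums(pr) - 1) > 1e-9 | apply(pr, 1, min) < -1e-12
  if (any(bad)) stopf("adapter produced invalid probability vectors")
  pr
}

#' Predict point values (regression) or hard labels (classification)
#'
#' For classification the point prediction is the maximum-probability label
#' (ties broken by label order); this is the "non-conformalized" base model
#' prediction that conformal error detection is measured against.
#'
#' @param fitted a `fitted_adapter`.
#' @param x feature matrix.
#' @return numeric vector (regression) or character vector of labels.
#' @export
predict_point <- function(fitted, x) {
  x <- as.matrix(x)
  if (fitted$task == "regression") {
    return(as.numeric(fitted$adapter$predict_point(fitted$model, x)))
  }
  pr <- predict_prob(fitted, x)
  fitted$label_space[max.col(pr, ties.method = "first")]
}

# ---------------------------------------------------------------------------
# Shipped adapters

#' Nearest-centroid Gaussian classifier
#'
#' Fits per-class feature means and a pooled within-class variance; class
#' probabilities are a softmax of `-d^2/(2*sigma^2)` where `d` is the
#' Euclidean distance to each class centroid (log-sum-exp stabilised).
#' Deterministic, fast, and well-specified for the package's Gaussian
#' generators, which makes it the reference learner for validity simulations
#' and for small-sample transductive checks (see
#' [centroid_distance_measure()]).
#'
#' @return a [model_adapter()].
#' @export
nearest_centroid_adapter <- function() {
  model_adapter(
    name = "nearest_centroid", task = "classification",
    fit = function(x, y) {
      classes <- sort(unique(y))
      mu <- do.call(rbind, lapply(classes, function(cl) {
        colMeans(x[y == cl, , drop = FALSE])
      }))
      rownames(mu) <- classes
      ss <- 0
      for (cl in classes) {
        d <- sweep(x[y == cl, , drop = FALSE], 2, mu[cl, ])
        ss <- ss + sum(d^2)
      }
      df <- max(1L, (nrow(x) - length(classes)) * ncol(x))
      list(centroids = mu, sigma2 = max(ss / df, 1e-12))
    },
    predict_prob = function(model, x, label_space) {
      mu <- model$centroids[label_space, , drop = FALSE]
      d2 <- outer(rowSums(x^2), rep(1, nrow(mu))) -
        2 * x %*% t(mu) + outer(rep(1, nrow(x)), rowSums(mu^2))
      ll <- -d2 / (2 * model$sigma2)
      ll <- ll - apply(ll, 1, max)
      w <- exp(ll)
      w / rowSums(w)
    }
  )
}

#' Support vector machine adapter (binary)
#'
#' Radial-kernel SVM via \pkg{e1071}. Two-class probabilities are obtained by
#' a logistic link on the signed decision values, which is deterministic
#' across refits (rank-equivalent to the margin, which is what conformal
#' p-values consume). Multiclass probability output is not provided.
#'
#' @param cost soft-margin cost `C`.
#' @param gamma kernel width; `NULL` uses the e1071 default `1/ncol(x)`.
#' @return a [model_adapter()].
#' @export
svm_adapter <- function(cost = 1, gamma = NULL) {
  model_adapter(
    name = "svm", task = "classification",
    params = list(cost = cost, gamma = gamma),
    fit = function(x, y) {
      classes <- sort(unique(y))
      if (length(classes) > 2) stopf("svm_adapter provides probabilities for binary problems only")
      args <- list(x = x, y = factor(y, levels = classes), kernel = "radial",
                   cost = cost, scale = FALSE)
      if (!is.null(gamma)) args$gamma <- gamma
      do.call(e1071::svm, args)
    },
    predict_prob = function(model, x, label_space) {
      pred <- stats::predict(model, x, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      pos <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      p_pos <- stats::plogis(dv[, 1])
      pr <- cbind(p_pos, 1 - p_pos)
      colnames(pr) <- c(pos, setdiff(label_space, pos))
      pr[, label_space, drop = FALSE]
    }
  )
}

#' Gradient-boosted trees adapter
#'
#' Multiclass (softprob) XGBoost, single-threaded for reproducibility.
#'
#' @param nrounds boosting rounds.
#' @param max_depth tree depth.
#' @param eta learning rate.
#' @return a [model_adapter()].
#' @export
xgboost_adapter <- function(nrounds = 60, max_depth = 3, eta = 0.3) {
  model_adapter(
    name = "xgboost", task = "classification",
    params = list(nrounds = nrounds, max_depth = max_depth, eta = eta),
    fit = function(x, y) {
      classes <- sort(unique(y))
      ylab <- match(y, classes) - 1L
      booster <- xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(classes),
                      max_depth = max_depth, eta = eta, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = ylab, nthread = 1),
        nrounds = nrounds, verbose = 0
      )
      list(booster = booster, classes = classes)
    },
    predict_prob = function(model, x, label_space) {
      pr <- stats::predict(model$booster,
                           xgboost::xgb.DMatrix(x, nthread = 1))
      if (!is.matrix(pr)) {
        pr <- matrix(pr, nrow = nrow(x), ncol = length(model$classes),
                     byrow = TRUE)
      }
      colnames(pr) <- model$classes
      pr <- pr / rowSums(pr)
      pr[, label_space, drop = FALSE]
    }
  )
}

#' Random forest adapter
#'
#' \pkg{randomForest} for classification (vote fractions as probabilities)
#' or regression (mean tree prediction). Training randomness is governed by
#' the seed passed to [adapter_fit()].
#'
#' @param task `"regression"` (default, as used for IC50 prediction) or
#'   `"classification"`.
#' @param ntree number of trees.
#' @param mtry variables tried per split; `NULL` uses the package default.
#' @param log_target fit the forest on `log(y)` and back-transform
#'   predictions with `exp` — the standard choice for strictly positive,
#'   heavy-tailed responses such as IC50, where a forest fit on the raw scale
#'   cannot track the tail. Regression only.
#' @return a [model_adapter()].
#' @export
random_forest_adapter <- function(task = "regression", ntree = 300,
                                  mtry = NULL, log_target = FALSE) {
  task <- match.arg(task, c("regression", "classification"))
  if (task == "regression") {
    model_adapter(
      name = if (log_target) "random_forest_log" else "random_forest",
      task = "regression",
      params = list(ntree = ntree, mtry = mtry, log_target = log_target),
      fit = function(x, y) {
        if (log_target) {
          if (any(y <= 0)) stopf("log_target requires strictly positive responses")
          y <- log(y)
        }
        args <- list(x = x, y = y, ntree = ntree)
        if (!is.null(mtry)) args$mtry <- mtry
        do.call(randomForest::randomForest, args)
      },
      predict_point = function(model, x) {
        p <- as.numeric(stats::predict(model, x))
        if (log_target) exp(p) else p
      }
    )
  } else {
    model_adapter(
      name = "random_forest", task = "classification",
      params = list(ntree = ntree, mtry = mtry),
      fit = function(x, y) {
        args <- list(x = x, y = factor(y, levels = sort(unique(y))), ntree = ntree)
        if (!is.null(mtry)) args$mtry <- mtry
        do.call(randomForest::randomForest, args)
      },
      predict_prob = function(model, x, label_space) {
        pr <- stats::predict(model, x, type = "prob")
        # guard against zero-vote degenerate rows
        pr <- (pr + 1e-9) / rowSums(pr + 1e-9)
        pr[, label_space, drop = FALSE]
      }
    )
  }
}

#' Linear model adapter (regression)
#'
#' Ordinary least squares; deterministic and exact on noiseless linear
#' responses, which makes it the reference learner for degenerate-interval
#' checks.
#'
#' @return a [model_adapter()].
#' @export
linear_adapter <- function() {
  model_adapter(
    name = "linear", task = "regression",
    fit = function(x, y) {
      df <- as.data.frame(x)
      names(df) <- paste0("V", seq_len(ncol(x)))
      stats::lm(y ~ ., data = cbind(df, y = y))
    },
    predict_point = function(model, x) {
      df <- as.data.frame(x)
      names(df) <- paste0("V", seq_len(ncol(x)))
      as.numeric(stats::predict(model, newdata = df))
    }
  )
}

# ---------------------------------------------------------------------------
# Grid search

#' Grid-based hyperparameter tuning by seeded cross-validation
#'
#' Evaluates a small named grid by k-fold cross-validation on the training
#' portion only (accuracy for classification, mean squared error for
#' regression) and returns the adapter built from the best cell. Ties go to
#' the earlier grid row, so tuning is deterministic under the seed.
#'
#' @param factory `function(...)` building a [model_adapter()] from one grid
#'   row, e.g. [svm_adapter].
#' @param grid data.frame of hyperparameter combinations (one row per cell).
#' @param x training feature matrix.
#' @param y training labels.
#' @param n_folds folds (default 5).
#' @param seed seed for fold assignment and fits.
#' @return list with `adapter` (the winning adapter), `best` (its grid row),
#'   and `scores` (per-cell CV score; higher is better).
#' @export
tune_grid <- function(factory, grid, x, y, n_folds = 5, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  n_folds <- min(n_folds, n)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  classification <- !is.numeric(y)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    adapter <- do.call(factory, as.list(grid[g, , drop = FALSE]))
    sc <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      if (classification && length(unique(y[tr])) < length(unique(y))) {
        # a fold that drops a class entirely is skipped
        sc[f] <- NA_real_
        next
      }
      fit <- adapter_fit(adapter, x[tr, , drop = FALSE], y[tr], seed = seed,
                         label_space = if (classification) sort(unique(y)) else NULL)
      if (classification) {
        sc[f] <- mean(predict_point(fit, x[!tr, , drop = FALSE]) == y[!tr])
      } else {
        sc[f] <- -mean((predict_point(fit, x[!tr, , drop = FALSE]) - y[!tr])^2)
      }
    }
    scores[g] <- mean(sc, na.rm = TRUE)
  }
  best <- which.max(scores)
  list(adapter = do.call(factory, as.list(grid[best, , drop = FALSE])),
       best = grid[best, , drop = FALSE], scores = scores)
}

#' Default hyperparameter grids
#'
#' The small fixed grids searched by the pipelines: SVM cost in
#' `{0.1, 1, 10}`; XGBoost depth in `{2, 4}`; random forest `ntree = 300`
#' with default and reduced `mtry`.
#'
#' @param model one of `"svm"`, `"xgboost"`, `"random_forest"`.
#' @return list with elements `factory` and `grid`.
#' @export
default_grid <- function(model) {
  switch(match.arg(model, c("svm", "xgboost", "random_forest")),
    svm = list(factory = svm_adapter,
               grid = data.frame(cost = c(0.1, 1, 10))),
    xgboost = list(factory = xgboost_adapter,
                   grid = data.frame(nrounds = c(60, 60), max_depth = c(2, 4))),
    random_forest = list(factory = random_forest_adapter,
                         grid = data.frame(ntree = c(200, 400)))
  )
}
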