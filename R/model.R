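#' Random-forest hyperparameter grid
#'
#' The exhaustive tuning grid for the MoCA-estimation forest: maximum tree
#' depth in \{2, 3, 4\}, maximum number of features per split in
#' \{2, 3, 4, 6\}, bootstrap sample fraction in \{1.0, 0.75, 0.5\} and
#' minimum samples per leaf in \{2, 3, 4, 5\} — a Cartesian product of 144
#' combinations, each fit with 500 trees. Rows are enumerated depth-major
#' (depth slowest, then max features, then sample fraction, then leaf size),
#' which also defines the deterministic tie-break order during tuning.
#'
#' @param max_depth,max_features,max_samples_fraction,min_samples_leaf
#'   Candidate values.
#' @return A data frame of hyperparameter combinations with attribute
#'   `n_trees`.
#' @export
hyper_grid <- function(max_depth = c(2L, 3L, 4L),
                       max_features = c(2L, 3L, 4L, 6L),
                       max_samples_fraction = c(1, 0.75, 0.5),
                       min_samples_leaf = c(2L, 3L, 4L, 5L)) {
  g <- expand.grid(min_samples_leaf = min_samples_leaf,
                   max_samples_fraction = max_samples_fraction,
                   max_features = max_features,
                   max_depth = max_depth,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("max_depth", "max_features", "max_samples_fraction",
             "min_samples_leaf")]
  rownames(g) <- NULL
  structure(g, n_trees = 500L)
}

fit_forest <- function(X, y, pars, n_trees, seed) {
  ranger::ranger(
    x = X, y = y,
    num.trees = n_trees,
    mtry = min(pars$max_features, ncol(X)),
    min.node.size = pars$min_samples_leaf,
    max.depth = pars$max_depth,
    sample.fraction = pars$max_samples_fraction,
    replace = TRUE,
    num.threads = 1L,
    seed = seed,
    oob.error = FALSE,
    verbose = FALSE)
}

predict_forest <- function(model, X) {
  stats::predict(model, data = as.data.frame(X),
                 num.threads = 1L, verbose = FALSE)$predictions
}

#' Tune and fit the MoCA-estimation forest
#'
#' Exhaustive grid search over all hyperparameter combinations by k-fold
#' cross-validation within the training data. Fold assignment is seeded and
#' shuffled once; the selection criterion is the lowest mean cross-validated
#' squared error (pooled over held-out predictions), with ties broken by the
#' first combination in the grid's deterministic enumeration order. The final
#' model is refit on all training data with the chosen combination.
#'
#' @param X Training feature matrix or data frame (six drawing features).
#' @param y Training MoCA scores.
#' @param grid A [hyper_grid()].
#' @param cv_folds Number of cross-validation folds.
#' @param seed Integer seed controlling fold assignment and tree randomness.
#' @return An object of class `rf_fit`: list with `model` (ranger object),
#'   `best` (chosen hyperparameter row), `cv_results` (all combinations with
#'   their CV mean squared error and tree count), `n_trees`, `folds`.
#' @export
tune_and_fit <- function(X, y, grid = hyper_grid(), cv_folds = 10L, seed = 1L) {
  X <- as.data.frame(X)
  n <- nrow(X)
  if (n < cv_folds) stop("need at least as many samples as folds", call. = FALSE)
  if (any(!is.finite(as.matrix(X))) || any(!is.finite(y))) {
    stop("non-finite values in features or targets", call. = FALSE)
  }
  n_trees <- attr(grid, "n_trees") %||% 500L
  n_comb <- nrow(grid)
  with_seed(seed, {
    folds <- sample(rep(seq_len(cv_folds), length.out = n))
    fit_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   n_comb * cv_folds), nrow = n_comb)
    final_seed <- sample.int(.Machine$integer.max - 1L, 1L)

    cv_mse <- numeric(n_comb)
    for (i in seq_len(n_comb)) {
      sse <- 0
      for (f in seq_len(cv_folds)) {
        tr <- folds != f
        m <- fit_forest(X[tr, , drop = FALSE], y[tr], grid[i, ],
                        n_trees, fit_seeds[i, f])
        pred <- predict_forest(m, X[!tr, , drop = FALSE])
        sse <- sse + sum((pred - y[!tr])^2)
      }
      cv_mse[i] <- sse / n
    }
    best_i <- which.min(cv_mse)
    model <- fit_forest(X, y, grid[best_i, ], n_trees, final_seed)

    cv_results <- cbind(as.data.frame(grid), cv_mse = cv_mse,
                        n_trees = n_trees)
    structure(list(model = model, best = grid[best_i, ],
                   best_index = best_i, cv_results = cv_results,
                   n_trees = n_trees, folds = folds, seed = as.integer(seed),
                   feature_names = colnames(X)),
              class = "rf_fit")
  })
}

#' @export
print.rf_fit <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<rf_fit> %d trees; depth %d, mtry %d, sample fraction %g, min leaf %d (CV MSE %.3f)\n",
    x$n_trees, b$max_depth, b$max_features, b$max_samples_fraction,
    b$min_samples_leaf, x$cv_results$cv_mse[x$best_index]))
  invisible(x)
}

#' Evaluate a fitted model on a held-out cohort
#'
#' Computes the coefficient of determination `R^2 = 1 - SSres/SStot` (with
#' SStot taken about the test-set mean — the convention under which R^2 and
#' the squared Pearson correlation can legitimately diverge), the Pearson
#' correlation between predicted and observed scores, the mean absolute
#' error and the root-mean-square error.
#'
#' @param fit An `rf_fit` (or any object accepted by [predict_forest] via its
#'   `model` element).
#' @param X_test,y_test Held-out features and MoCA scores.
#' @return Named list `r2`, `pearson_r`, `mae`, `rmse`.
#' @export
evaluate_model <- function(fit, X_test, y_test) {
  if (length(y_test) == 0L) stop("empty test set", call. = FALSE)
  model <- if (inherits(fit, "rf_fit")) fit$model else fit
  regression_metrics(predict_forest(model, X_test), y_test)
}

#' @rdname evaluate_model
#' @param predictions,observed Paired prediction/truth vectors, for computing
#'   the metrics directly.
#' @export
regression_metrics <- function(predictions, observed) {
  if (length(observed) == 0L) stop("empty test set", call. = FALSE)
  if (stats::var(observed) == 0) {
    stop("zero-variance test targets: R^2 undefined", call. = FALSE)
  }
  err <- predictions - observed
  r <- if (stats::sd(predictions) == 0) NA_real_ else
    stats::cor(predictions, observed)
  list(r2 = 1 - sum(err^2) / sum((observed - mean(observed))^2),
       pearson_r = r,
       mae = mean(abs(err)),
       rmse = sqrt(mean(err^2)))
}

#' Permutation test of cross-cohort estimation performance
#'
#' Assesses whether the observed test-set statistic (R^2 by default) exceeds
#' what forests trained on cognitively meaningless labels achieve: each
#' iteration permutes the training MoCA scores uniformly at random, refits
#' the forest with the already-chosen hyperparameters (no re-tuning by
#' default), and evaluates on the intact test set. The p-value uses the
#' add-one estimator `(1 + #{perm >= observed}) / (1 + B)`, bounded below by
#' `1/(B+1)`.
#'
#' @param fit An `rf_fit` from [tune_and_fit()].
#' @param X_train,y_train Training data used to refit under permuted labels.
#' @param X_test,y_test Held-out evaluation data.
#' @param n_permutations Number of label permutations B.
#' @param statistic Which test statistic to use: `"r2"` or `"pearson_r"`.
#' @param seed Integer seed for the permutation stream.
#' @param retune Re-run the full grid search for every permutation instead of
#'   reusing the chosen hyperparameters (much slower; off by default).
#' @param cv_folds Folds used when `retune = TRUE`.
#' @return List with `p`, `observed`, `perm_stats` (length B), `statistic`,
#'   `n_permutations`.
#' @export
permutation_test <- function(fit, X_train, y_train, X_test, y_test,
                             n_permutations = 1000L,
                             statistic = c("r2", "pearson_r"),
                             seed = 1L, retune = FALSE, cv_folds = 10L) {
  statistic <- match.arg(statistic)
  if (n_permutations < 1L) stop("need at least one permutation", call. = FALSE)
  X_train <- as.data.frame(X_train)
  observed <- evaluate_model(fit, X_test, y_test)[[statistic]]
  with_seed(seed, {
    fit_seeds <- sample.int(.Machine$integer.max - 1L, n_permutations)
    perm_stats <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      y_perm <- sample(y_train)
      m <- if (retune) {
        tune_and_fit(X_train, y_perm,
                     grid = fit$cv_results[, 1:4] |> (\(g) {
                       attr(g, "n_trees") <- fit$n_trees; g })(),
                     cv_folds = cv_folds, seed = fit_seeds[b])$model
      } else {
        fit_forest(X_train, y_perm, fit$best, fit$n_trees, fit_seeds[b])
      }
      pred <- predict_forest(m, X_test)
      perm_stats[b] <- if (statistic == "r2") {
        1 - sum((pred - y_test)^2) / sum((y_test - mean(y_test))^2)
      } else if (stats::sd(pred) == 0) {
        0 # degenerate constant predictor carries no association
      } else {
        stats::cor(pred, y_test)
      }
    }
    list(p = (1 + sum(perm_stats >= observed)) / (1 + n_permutations),
         observed = observed, perm_stats = perm_stats,
         statistic = statistic, n_permutations = as.integer(n_permutations))
  })
}

#' Exact Shapley feature attributions for a fitted forest
#'
#' Computes exact Shapley values by enumerating all 2^p feature coalitions
#' (feasible for the six drawing features). The value of a coalition S for a
#' sample x is the interventional expectation of the model output with the
#' features in S fixed at x and the remaining features drawn from the
#' background data. By construction the attributions satisfy the additivity
#' axiom exactly: for every sample, `base_value + sum(attributions)` equals
#' the model prediction.
#'
#' @param fit An `rf_fit` (or a bare ranger model).
#' @param data Data frame or matrix of samples to explain.
#' @param background Background data defining the reference distribution
#'   (defaults to `data`).
#' @param max_background Cap on background rows; if exceeded, an evenly
#'   spaced deterministic subset is used.
#' @return An object of class `shapley_attribution`: list with
#'   `attributions` (samples x features matrix), `base_value`, `predictions`,
#'   and `importance` — a data frame of per-feature mean absolute
#'   attributions with standard deviations, sorted decreasing.
#' @export
shapley_importance <- function(fit, data, background = data,
                               max_background = 200L) {
  model <- if (inherits(fit, "rf_fit")) fit$model else fit
  data <- as.data.frame(data)
  background <- as.data.frame(background)
  p <- ncol(data)
  if (p > 12L) stop("exact coalition enumeration limited to 12 features",
                    call. = FALSE)
  if (nrow(data) == 0L || nrow(background) == 0L) {
    stop("data and background must be nonempty", call. = FALSE)
  }
  if (nrow(background) > max_background) {
    keep <- unique(round(seq(1L, nrow(background),
                             length.out = max_background)))
    background <- background[keep, , drop = FALSE]
  }
  nfg <- nrow(data); nbg <- nrow(background)
  coal <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p),
                                KEEP.OUT.ATTRS = FALSE))
  n_coal <- nrow(coal)

  V <- matrix(0, nfg, n_coal)
  bg_rep <- background[rep(seq_len(nbg), times = nfg), , drop = FALSE]
  for (ci in seq_len(n_coal)) {
    S <- coal[ci, ]
    if (!any(S)) {
      V[, ci] <- mean(predict_forest(model, background))
    } else if (all(S)) {
      V[, ci] <- predict_forest(model, data)
    } else {
      mixed <- bg_rep
      mixed[, S] <- data[rep(seq_len(nfg), each = nbg), S, drop = FALSE]
      pred <- predict_forest(model, mixed)
      V[, ci] <- rowMeans(matrix(pred, nfg, nbg, byrow = TRUE))
    }
  }

  pow2 <- 2^(seq_len(p) - 1L)
  phi <- matrix(0, nfg, p, dimnames = list(NULL, colnames(data)))
  wts <- factorial(0:(p - 1L)) * factorial(p - 1L - 0:(p - 1L)) / factorial(p)
  for (j in seq_len(p)) {
    without_j <- which(!coal[, j])
    for (ci in without_j) {
      s <- sum(coal[ci, ])
      cj <- ci + pow2[j]
      phi[, j] <- phi[, j] + wts[s + 1L] * (V[, cj] - V[, ci])
    }
  }

  mean_abs <- colMeans(abs(phi))
  sd_abs <- apply(abs(phi), 2L, stats::sd)
  importance <- data.frame(feature = colnames(data),
                           mean_abs_shap = mean_abs, sd_abs_shap = sd_abs,
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$mean_abs_shap), ]
  rownames(importance) <- NULL
  structure(list(attributions = phi, base_value = V[1L, 1L],
                 predictions = V[, n_coal], importance = importance),
            class = "shapley_attribution")
}

#' @export
print.shapley_attribution <- function(x, ...) {
  cat(sprintf("<shapley_attribution> %d samples, base value %.3f\n",
              nrow(x$attributions), x$base_value))
  print(transform(x$importance,
                  mean_abs_shap = round(mean_abs_shap, 4),
                  sd_abs_shap = round(sd_abs_shap, 4)))
  invisible(x)
}
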