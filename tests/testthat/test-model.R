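small_grid <- function() {
  hyper_grid(max_depth = c(2L, 3L), max_features = 2L,
             max_samples_fraction = 1, min_samples_leaf = c(2L, 5L))
}

sim_xy <- function(n, seed, noise = 1) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(X) <- drawing_feature_names()
  y <- 24 + 2 * X$speed_cv - 1.5 * X$pause_ratio + noise * rnorm(n)
  list(X = X, y = y)
}

test_that("the hyperparameter grid is the full depth-major product", {
  g <- hyper_grid()
  expect_equal(nrow(g), 144L)
  expect_equal(attr(g, "n_trees"), 500L)
  expect_equal(nrow(unique(g)), 144L)
  # depth-major enumeration: depth varies slowest, leaf size fastest
  expect_equal(g$max_depth[1:48], rep(2L, 48))
  expect_equal(g$min_samples_leaf[1:4], c(2L, 3L, 4L, 5L))
  expect_true(all(g$max_features <= 6))
})

test_that("a constant training target ties all combinations to the first", {
  set.seed(6)
  X <- as.data.frame(matrix(rnorm(120), 20, 6))
  names(X) <- drawing_feature_names()
  fit <- tune_and_fit(X, rep(24, 20), grid = small_grid(), cv_folds = 5,
                      seed = 2)
  expect_equal(fit$best_index, 1L)
  expect_true(all(fit$cv_results$cv_mse == fit$cv_results$cv_mse[1]))
  expect_true(all(predict_forest(fit$model, X) == 24))
})

test_that("tuning recovers a noiseless monotone single-feature signal", {
  d <- sim_xy(200, seed = 7)
  y <- 24 + 3 * tanh(d$X$speed_cv) # noiseless, monotone in one feature
  fit <- tune_and_fit(d$X[1:150, ], y[1:150],
                      grid = hyper_grid(max_depth = 4L, max_features = 6L,
                                        max_samples_fraction = 1,
                                        min_samples_leaf = 2L),
                      cv_folds = 5, seed = 3)
  m <- evaluate_model(fit, d$X[151:200, ], y[151:200])
  expect_gt(m$r2, 0.8)
})

test_that("tuning is deterministic and rejects invalid input", {
  d <- sim_xy(40, seed = 8)
  f1 <- tune_and_fit(d$X, d$y, grid = small_grid(), cv_folds = 5, seed = 4)
  f2 <- tune_and_fit(d$X, d$y, grid = small_grid(), cv_folds = 5, seed = 4)
  expect_identical(f1$best, f2$best)
  expect_identical(f1$cv_results, f2$cv_results)
  expect_identical(predict_forest(f1$model, d$X),
                   predict_forest(f2$model, d$X))

  expect_error(tune_and_fit(d$X[1:5, ], d$y[1:5], cv_folds = 10), "folds")
  bad <- d$X; bad[1, 1] <- NA
  expect_error(tune_and_fit(bad, d$y, grid = small_grid(), cv_folds = 5),
               "non-finite")
})

test_that("evaluation metrics follow their definitions", {
  y <- c(24, 26, 22, 28)
  perfect <- regression_metrics(y, y)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)

  mean_only <- regression_metrics(rep(mean(y), 4), y)
  expect_equal(mean_only$r2, 0)

  hand <- regression_metrics(c(25, 24), c(24, 26))
  expect_equal(hand$mae, 1.5)
  expect_equal(hand$rmse, sqrt(5 / 2))
  expect_gte(hand$rmse, hand$mae)

  expect_error(regression_metrics(c(1, 2), c(5, 5)), "zero-variance")
})

test_that("permutation p attains its formula bounds", {
  # strong signal: observed beats all permutations -> p = 1/(B+1)
  d <- sim_xy(80, seed = 9, noise = 0.2)
  tr <- 1:60; te <- 61:80
  fit <- tune_and_fit(d$X[tr, ], d$y[tr], grid = small_grid(), cv_folds = 5,
                      seed = 5)
  B <- 19
  pt <- permutation_test(fit, d$X[tr, ], d$y[tr], d$X[te, ], d$y[te],
                         n_permutations = B, seed = 6)
  expect_equal(pt$p, 1 / (B + 1))
  expect_equal(length(pt$perm_stats), B)

  # anti-signal test target: observed below every permutation -> p = 1
  y_anti <- -3 * d$X$speed_cv[te] + 24
  pt2 <- permutation_test(fit, d$X[tr, ], d$y[tr], d$X[te, ], y_anti,
                          n_permutations = B, seed = 7)
  expect_equal(pt2$p, 1)

  # determinism
  pt3 <- permutation_test(fit, d$X[tr, ], d$y[tr], d$X[te, ], d$y[te],
                          n_permutations = B, seed = 6)
  expect_identical(pt$perm_stats, pt3$perm_stats)
})

test_that("re-tuning permutations run when requested", {
  d <- sim_xy(30, seed = 10)
  tr <- 1:20; te <- 21:30
  fit <- tune_and_fit(d$X[tr, ], d$y[tr], grid = small_grid(), cv_folds = 4,
                      seed = 8)
  pt <- permutation_test(fit, d$X[tr, ], d$y[tr], d$X[te, ], d$y[te],
                         n_permutations = 2, seed = 9, retune = TRUE,
                         cv_folds = 4)
  expect_true(pt$p >= 1 / 3 - 1e-12 && pt$p <= 1)
})

test_that("Shapley attributions satisfy additivity and ignore constants", {
  d <- sim_xy(60, seed = 11)
  d$X$incl_v_sd <- 1 # constant feature
  fit <- tune_and_fit(d$X, d$y, grid = small_grid(), cv_folds = 5, seed = 10)
  sh <- shapley_importance(fit, d$X[1:25, ], background = d$X)
  recon <- sh$base_value + rowSums(sh$attributions)
  expect_lt(max(abs(recon - sh$predictions)), 1e-6)
  expect_lt(max(abs(sh$predictions - predict_forest(fit$model, d$X[1:25, ]))),
            1e-9)
  expect_equal(
    sh$importance$mean_abs_shap[sh$importance$feature == "incl_v_sd"], 0)
})

test_that("attributions match the brute-force coalition oracle", {
  # depth-1 forest on 2 features
  set.seed(12)
  X2 <- data.frame(a = rnorm(80), b = rnorm(80))
  y2 <- ifelse(X2$a > 0, 28, 20) + 0.1 * rnorm(80)
  m <- ranger::ranger(x = X2, y = y2, num.trees = 30, max.depth = 1,
                      mtry = 2, num.threads = 1, seed = 1,
                      oob.error = FALSE)
  sh <- shapley_importance(m, X2[1:6, ], background = X2)
  for (i in 1:6) {
    want <- oracle_shapley_row(m, X2[i, ], X2)
    expect_equal(unname(sh$attributions[i, ]), want, tolerance = 1e-9)
  }

  # six-feature model against the same oracle on one sample
  d <- sim_xy(50, seed = 13)
  fit <- tune_and_fit(d$X, d$y, grid = small_grid(), cv_folds = 5, seed = 11)
  sh6 <- shapley_importance(fit, d$X[1:2, ], background = d$X[1:30, ])
  want6 <- oracle_shapley_row(fit$model, d$X[1, ], d$X[1:30, ])
  expect_equal(unname(sh6$attributions[1, ]), want6, tolerance = 1e-9)
})

test_that("signal-bearing features rank top of the Shapley importances", {
  eff <- effect_config(assoc = c(speed_mean = 0, speed_cv = -0.5,
                                 pressure_mad = 0, incl_h_sd = 0,
                                 incl_v_sd = 0, pause_ratio = -0.5))
  hits <- 0L
  for (seed in 1:10) {
    rec <- quick_records(120, 60, effect = eff, seed = 40 + seed,
                         session = tiny_session())
    fn <- drawing_feature_names()
    tr <- rec$cohort == "US-like"
    fit <- tune_and_fit(rec[tr, fn], rec$moca[tr],
                        grid = hyper_grid(max_depth = 4L, max_features = 2L,
                                          max_samples_fraction = 1,
                                          min_samples_leaf = 5L),
                        cv_folds = 5, seed = seed)
    sh <- shapley_importance(fit, rec[!tr, fn][1:40, ],
                             background = rec[tr, fn][1:40, ])
    top2 <- sh$importance$feature[1:2]
    if (setequal(top2, c("speed_cv", "pause_ratio"))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
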