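#' Configuration for a full cross-cohort analysis run
#'
#' A single object holding everything a full run depends on: the device
#' profile, the two cohort configurations, the effect configuration, the
#' session kinematic baselines, the hyperparameter grid, the permutation
#' budget, and the per-stage seeds (generation, folds, permutation), all
#' derived deterministically from one master seed.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param cohort_train,cohort_test The training and testing
#'   [cohort_config()]s (defaults: US-like n=55 and Japan-like n=37).
#' @param effect An [effect_config()].
#' @param device A [device_profile()].
#' @param session A [session_defaults()].
#' @param grid A [hyper_grid()].
#' @param cv_folds Cross-validation folds for tuning.
#' @param n_permutations Label permutations for the significance test.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       cohort_train = cohort_config_us(),
                       cohort_test = cohort_config_japan(),
                       effect = effect_config(),
                       device = device_profile(),
                       session = session_defaults(),
                       grid = hyper_grid(),
                       cv_folds = 10L,
                       n_permutations = 1000L) {
  if (identical(cohort_train$name, cohort_test$name)) {
    stop("cohorts must have distinct names", call. = FALSE)
  }
  seeds <- derive_seeds(seed, 4L)
  structure(list(seed = as.integer(seed),
                 seeds = list(generation_train = seeds[1L],
                              generation_test = seeds[2L],
                              folds = seeds[3L],
                              permutation = seeds[4L]),
                 cohort_train = cohort_train, cohort_test = cohort_test,
                 effect = effect, device = device, session = session,
                 grid = grid, cv_folds = as.integer(cv_folds),
                 n_permutations = as.integer(n_permutations)),
            class = "run_config")
}

#' Run the full cross-cohort drawing analysis
#'
#' Executes the complete workflow on synthetic cohorts: simulate raw pen
#' streams for both cohorts, extract the six drawing features, compute
#' demographic contrasts and covariate-adjusted feature-MoCA correlation
#' tables (pooled and per cohort, Benjamini-Hochberg corrected within each
#' six-test family), tune and fit the random forest on the training cohort,
#' evaluate it on the testing cohort, run the permutation test, and compute
#' exact Shapley feature importances (test-cohort samples explained against
#' the training cohort as background). Deterministic given the config.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress to stderr.
#' @return An object of class `run_report`: list with `records`,
#'   `demographics`, `correlations` (named list `all`, plus one table per
#'   cohort), `model` (chosen hyperparameters and CV table), `metrics`
#'   (r2, pearson_r, mae, rmse), `permutation` (p, observed, perm_stats),
#'   `importance`, `attributions` and `provenance`.
#' @export
run_full <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(stage) {
    if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                 stage))
  }
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e) {
      stop_stage(name, conditionMessage(e))
    })
  }

  train <- stage("simulate/train", generate_cohort(
    config$cohort_train, config$effect, config$device,
    seed = config$seeds$generation_train, session = config$session,
    keep_streams = FALSE, extract = TRUE))
  test <- stage("simulate/test", generate_cohort(
    config$cohort_test, config$effect, config$device,
    seed = config$seeds$generation_test, session = config$session,
    keep_streams = FALSE, extract = TRUE))

  records <- stage("records", participant_records(train, test))
  demographics <- stage("demographics", cohort_compare(records))
  correlations <- stage("correlate", {
    tabs <- list(all = feature_moca_table(records))
    for (nm in unique(records$cohort)) {
      tabs[[nm]] <- feature_moca_table(records[records$cohort == nm, ])
    }
    tabs
  })

  fn <- drawing_feature_names()
  X_train <- records[records$cohort == config$cohort_train$name, fn]
  y_train <- records$moca[records$cohort == config$cohort_train$name]
  X_test <- records[records$cohort == config$cohort_test$name, fn]
  y_test <- records$moca[records$cohort == config$cohort_test$name]

  fit <- stage("train", tune_and_fit(X_train, y_train, grid = config$grid,
                                     cv_folds = config$cv_folds,
                                     seed = config$seeds$folds))
  metrics <- stage("evaluate", evaluate_model(fit, X_test, y_test))
  perm <- stage("permutation", permutation_test(
    fit, X_train, y_train, X_test, y_test,
    n_permutations = config$n_permutations,
    seed = config$seeds$permutation))
  shap <- stage("importance", shapley_importance(fit, X_test,
                                                 background = X_train))

  provenance <- list(
    config_digest = rlang::hash(config),
    seed = config$seed, seeds = config$seeds,
    package_version = as.character(utils::packageVersion("drawcog")))

  structure(list(records = records, demographics = demographics,
                 correlations = correlations,
                 model = list(best = fit$best,
                              cv_results = fit$cv_results,
                              n_trees = fit$n_trees),
                 metrics = metrics, permutation = perm,
                 importance = shap$importance,
                 attributions = shap$attributions,
                 base_value = shap$base_value,
                 provenance = provenance),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  cohorts: %s\n",
              paste(unique(x$records$cohort), collapse = " -> ")))
  cat(sprintf("  n = %d participants\n", nrow(x$records)))
  m <- x$metrics
  cat(sprintf("  test R^2 = %.3f, Pearson r = %.3f, MAE = %.3f, RMSE = %.3f\n",
              m$r2, m$pearson_r, m$mae, m$rmse))
  cat(sprintf("  permutation p = %.4g (B = %d)\n", x$permutation$p,
              x$permutation$n_permutations))
  cat("  pooled feature-MoCA partial correlations:\n")
  tab <- x$correlations$all
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("    %-13s r = %+.3f (%.3f, %.3f)  p_bh = %.4g\n",
                tab$feature[i], tab$r[i], tab$ci_low[i], tab$ci_high[i],
                tab$p_bh[i]))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes the report as a JSON summary plus CSV tables (records,
#' correlations, permutation trace, importances, attribution matrix) under
#' `dir`.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(metrics = report$metrics,
                  permutation_p = report$permutation$p,
                  observed_statistic = report$permutation$observed,
                  chosen_hyperparameters = as.list(report$model$best),
                  n_trees = report$model$n_trees,
                  provenance = report$provenance)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  corr <- do.call(rbind, lapply(names(report$correlations), function(nm) {
    cbind(subset_name = nm, report$correlations[[nm]])
  }))
  utils::write.csv(corr, file.path(dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(report$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(perm_stat = report$permutation$perm_stats),
                   file.path(dir, "permutation_trace.csv"), row.names = FALSE)
  utils::write.csv(report$importance, file.path(dir, "importance.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$attributions),
                   file.path(dir, "attributions.csv"), row.names = FALSE)
  invisible(dir)
}
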