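#' Read and write run configurations as YAML
#'
#' Serializes a [run_config()] — device profile, both cohort configurations,
#' effect configuration, session baselines, grid ranges, folds, permutation
#' budget and master seed — to a YAML file, the single source of truth for a
#' reproducible run.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  cc <- function(ch) {
    list(name = ch$name, n_participants = ch$n_participants,
         age_mean_years = ch$age_mean_years, age_sd_years = ch$age_sd_years,
         prop_female = ch$prop_female,
         edu_mean_years = ch$edu_mean_years, edu_sd_years = ch$edu_sd_years,
         moca_mean = ch$moca_mean, moca_sd = ch$moca_sd,
         moca_range = as.integer(ch$moca_range))
  }
  out <- list(
    seed = config$seed,
    device = unclass(config$device),
    cohort_train = cc(config$cohort_train),
    cohort_test = cc(config$cohort_test),
    effect = list(assoc = as.list(config$effect$assoc),
                  noise_sd = config$effect$noise_sd,
                  strength_scale = config$effect$strength_scale,
                  age_confound = config$effect$age_confound),
    session = unclass(config$session),
    grid = list(max_depth = unique(config$grid$max_depth),
                max_features = unique(config$grid$max_features),
                max_samples_fraction = unique(config$grid$max_samples_fraction),
                min_samples_leaf = unique(config$grid$min_samples_leaf)),
    cv_folds = config$cv_folds,
    n_permutations = config$n_permutations)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  ch <- function(l) {
    cohort_config(l$name, l$n_participants, l$age_mean_years, l$age_sd_years,
                  l$prop_female, l$edu_mean_years, l$edu_sd_years,
                  l$moca_mean, l$moca_sd, unlist(l$moca_range))
  }
  run_config(
    seed = y$seed,
    cohort_train = ch(y$cohort_train),
    cohort_test = ch(y$cohort_test),
    effect = effect_config(assoc = unlist(y$effect$assoc),
                           noise_sd = y$effect$noise_sd,
                           strength_scale = y$effect$strength_scale,
                           age_confound = y$effect$age_confound %||% 0),
    device = do.call(device_profile, y$device),
    session = do.call(session_defaults, y$session),
    grid = hyper_grid(max_depth = unlist(y$grid$max_depth),
                      max_features = unlist(y$grid$max_features),
                      max_samples_fraction = unlist(y$grid$max_samples_fraction),
                      min_samples_leaf = unlist(y$grid$min_samples_leaf)),
    cv_folds = y$cv_folds,
    n_permutations = y$n_permutations)
}

#' Write or read the cohort metadata CSV
#'
#' Columns: `participant_id`, `cohort`, `age`, `sex` (0/1, 1 = female),
#' `education_years`, `moca`.
#'
#' @param metadata Data frame (e.g. `generate_cohort()$metadata`).
#' @param path File path.
#' @return `read_metadata_csv()` returns the data frame;
#'   `write_metadata_csv()` returns `path` invisibly.
#' @export
write_metadata_csv <- function(metadata, path) {
  cols <- c("participant_id", "cohort", "age", "sex", "education_years",
            "moca")
  stopifnot(all(cols %in% names(metadata)))
  utils::write.csv(metadata[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("participant_id", "cohort", "age", "sex", "education_years",
            "moca")
  if (!all(cols %in% names(df))) {
    stop("metadata CSV missing required columns", call. = FALSE)
  }
  if (any(df$moca < 0 | df$moca > 30)) {
    stop("moca scores must lie in [0, 30]", call. = FALSE)
  }
  df[cols]
}
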