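#' Configuration for an end-to-end scenario run
#'
#' Bundles everything one modelling scenario needs: the data source (either a
#' [synthetic_config()] or paths to feature/clinical CSVs), the scenario
#' label, the sparsity grid and panel-size window for \eqn{\beta} selection,
#' network width, test fraction and the seeds for the split and the network
#' initialization.
#'
#' @param scenario one of `"CFI-CRC-CLM"`, `"CFI-CRC"`, `"CFI-mCRC"`.
#' @param synthetic optional [synthetic_config()] used to generate the cohort.
#' @param features_path,clinical_path,annotations_path,replicate_map_path
#'   CSV inputs, used when `synthetic` is `NULL`.
#' @param beta_grid non-empty, non-negative, strictly increasing sparsity
#'   values (default `c(0.1, 0.2, 0.3, 0.4, 0.6, 1.0)`, spanning the
#'   method's practical range on cohorts of this size).
#' @param feature_count_window advisory `c(min, max)` panel size for
#'   [choose_beta()] (default `c(9, 12)`).
#' @param brann_hidden hidden units for the network (default 3).
#' @param test_frac stratified test fraction (default 0.2).
#' @param seed_split,seed_brann integer seeds for the partition and the
#'   network initialization.
#' @param include_clinical append clinical/chemokine/gene columns; defaults
#'   to `TRUE` for the `CFI-mCRC` scenario and `FALSE` otherwise.
#' @param standardize_clinical z-score continuous clinical columns
#'   (default `TRUE`).
#' @param include_stage0 see [assemble_design()].
#' @param scale_factor intensity scaling divisor (default 1e5).
#' @param outlier_k_sd replicate outlier threshold (default 3).
#' @param impute_strategy imputation strategy (default `"feature-mean"`).
#' @return a `run_config` list.
#' @export
run_config <- function(scenario,
                       synthetic = NULL,
                       features_path = NULL, clinical_path = NULL,
                       annotations_path = NULL, replicate_map_path = NULL,
                       beta_grid = c(0.1, 0.2, 0.3, 0.4, 0.6, 1.0),
                       feature_count_window = c(9, 12),
                       brann_hidden = 3,
                       test_frac = 0.2,
                       seed_split = 1, seed_brann = 1,
                       include_clinical = identical(scenario, "CFI-mCRC"),
                       standardize_clinical = TRUE,
                       include_stage0 = FALSE,
                       scale_factor = 1e5,
                       outlier_k_sd = 3,
                       impute_strategy = "feature-mean") {
  ls_assert(scenario %in% scenario_labels,
            sprintf("`scenario` must be one of %s",
                    paste(scenario_labels, collapse = ", ")),
            "lipistage_config_error")
  ls_assert(length(beta_grid) > 0 && all(beta_grid >= 0) &&
              (length(beta_grid) == 1 || all(diff(beta_grid) > 0)),
            "`beta_grid` must be non-empty, non-negative and sorted increasing",
            "lipistage_config_error")
  ls_assert(!is.null(synthetic) ||
              (!is.null(features_path) && !is.null(clinical_path)),
            "provide either `synthetic` or `features_path` + `clinical_path`",
            "lipistage_config_error")
  structure(list(scenario = scenario, synthetic = synthetic,
                 features_path = features_path, clinical_path = clinical_path,
                 annotations_path = annotations_path,
                 replicate_map_path = replicate_map_path,
                 beta_grid = beta_grid,
                 feature_count_window = feature_count_window,
                 brann_hidden = brann_hidden, test_frac = test_frac,
                 seed_split = seed_split, seed_brann = seed_brann,
                 include_clinical = include_clinical,
                 standardize_clinical = standardize_clinical,
                 include_stage0 = include_stage0,
                 scale_factor = scale_factor, outlier_k_sd = outlier_k_sd,
                 impute_strategy = impute_strategy),
            class = "run_config")
}

load_study <- function(config) {
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    list(features = cohort$features, clinical = cohort$clinical,
         replicate_map = cohort$replicate_map, cohort = cohort)
  } else {
    features <- read_feature_table(config$features_path,
                                   config$annotations_path)
    clinical <- read_clinical_table(config$clinical_path)
    rmap <- if (!is.null(config$replicate_map_path)) {
      df <- utils::read.csv(config$replicate_map_path,
                            stringsAsFactors = FALSE)
      stats::setNames(as.character(df$sample_id), df$replicate_id)
    } else {
      stats::setNames(features$sample_ids, features$sample_ids)
    }
    list(features = features, clinical = clinical, replicate_map = rmap,
         cohort = NULL)
  }
}

preprocess_study <- function(features, clinical, replicate_map, config) {
  ft <- scale_intensities(features, config$scale_factor)
  masked <- mask_replicate_outliers(ft, replicate_map, config$outlier_k_sd)
  ft <- collapse_replicates(masked$features, replicate_map)
  ft <- impute_missing(ft, config$impute_strategy)
  study <- align(ft, clinical)
  study$n_outliers_masked <- sum(masked$outlier_mask)
  study
}

#' Run one modelling scenario end-to-end
#'
#' Executes the full analysis: data loading (or synthetic generation),
#' intensity scaling, replicate-outlier masking, replicate collapsing,
#' imputation, design assembly with the scenario's ordinal coding, a
#' stratified train/test split, the MLR-EM sparsity sweep on the training
#' partition only, \eqn{\beta} selection, post-selection t-tests, a BRANN
#' trained on the MLR-selected feature subset, evaluation of both models on
#' both partitions, and (when endpoints are present) Kaplan-Meier / log-rank
#' survival comparison. Identical configuration and seeds reproduce the
#' report byte-for-byte.
#'
#' @param config a [run_config()].
#' @return a `run_report` list: `scenario`, `chosen_beta`, `beta_rule`,
#'   `sweep_sizes`, `selected_features` (data.frame feature/coefficient/t/p),
#'   `mlr_eval` and `brann_eval` ([evaluation_report()]s), `survival`
#'   (log-rank summaries per endpoint or `NULL`), `seeds`, `software_version`
#'   and a config echo.
#' @export
run_scenario <- function(config) {
  ls_assert(inherits(config, "run_config"), "`config` must come from run_config()",
            "lipistage_config_error")
  src <- load_study(config)
  study <- preprocess_study(src$features, src$clinical, src$replicate_map,
                            config)
  dataset <- assemble_design(study, config$scenario,
                             include_clinical = config$include_clinical,
                             standardize_clinical = config$standardize_clinical,
                             include_stage0 = config$include_stage0)
  split <- stratified_split(dataset, config$test_frac, config$seed_split)

  sweep <- sparsity_sweep(split$train$X, split$train$y, config$beta_grid)
  sel <- choose_beta(sweep, config$feature_count_window)
  model <- sel$model

  yhat_train_mlr <- predict(model, split$train$X)
  yhat_test_mlr <- predict(model, split$test$X)
  classes <- sort(unique(dataset$y))
  mlr_eval <- evaluation_report(split$train$y, yhat_train_mlr,
                                split$test$y, yhat_test_mlr,
                                classes, config$seed_split)

  if (length(model$selected_features) > 0) {
    Xb_train <- split$train$X[, model$selected_features, drop = FALSE]
    Xb_test <- split$test$X[, model$selected_features, drop = FALSE]
    brann <- fit_brann(Xb_train, split$train$y,
                       n_hidden = config$brann_hidden,
                       seed = config$seed_brann)
    yhat_train_br <- predict(brann, Xb_train)
    yhat_test_br <- predict(brann, Xb_test)
  } else {
    brann <- NULL
    yhat_train_br <- rep(mean(split$train$y), length(split$train$y))
    yhat_test_br <- rep(mean(split$train$y), length(split$test$y))
  }
  brann_eval <- evaluation_report(split$train$y, yhat_train_br,
                                  split$test$y, yhat_test_br,
                                  classes, config$seed_split)

  surv <- NULL
  has_endpoints <- all(c("dfs_months", "dfs_event") %in% names(study$clinical))
  if (has_endpoints && any(study$clinical$group != "CFI")) {
    surv <- lapply(c(dfs = "dfs", os = "os"), function(ep) {
      res <- tryCatch(survival_by_group(study$clinical, ep),
                      lipistage_error = function(e) NULL)
      if (is.null(res) || is.null(res$logrank)) return(NULL)
      list(chi2 = res$logrank$chi2, df = res$logrank$df, p = res$logrank$p,
           degenerate = res$logrank$degenerate,
           groups = names(res$curves), at_risk = res$at_risk)
    })
  }

  structure(list(
    scenario = config$scenario,
    n_samples = nrow(dataset$X), n_columns = ncol(dataset$X),
    coding_map = dataset$coding_map,
    chosen_beta = sel$beta, beta_rule = sel$rule,
    sweep_sizes = data.frame(
      beta = vapply(sweep$entries, `[[`, numeric(1), "beta_sparsity"),
      n_selected = vapply(sweep$entries, `[[`, numeric(1), "n_selected")),
    selected_features = data.frame(
      feature = model$selected_features,
      coefficient = unname(model$coefficients),
      t = unname(model$t_stats), p = unname(model$p_values),
      stringsAsFactors = FALSE),
    degenerate = model$degenerate,
    mlr_eval = mlr_eval, brann_eval = brann_eval,
    brann_gamma = if (!is.null(brann)) brann$gamma_effective else NA_real_,
    survival = surv,
    seeds = list(split = config$seed_split, brann = config$seed_brann,
                 synthetic = if (!is.null(config$synthetic))
                   config$synthetic$seed else NULL),
    software_version = as.character(utils::packageVersion("lipistage")),
    config = config,
    models = list(mlr = model, brann = brann)
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> scenario %s (%d samples x %d columns)\n",
              x$scenario, x$n_samples, x$n_columns))
  cat(sprintf("  beta = %g (%s rule), %d feature(s) selected\n",
              x$chosen_beta, x$beta_rule, nrow(x$selected_features)))
  cat("  MLR-EM: "); print(x$mlr_eval)
  cat("  BRANN : "); print(x$brann_eval)
  if (!is.null(x$survival)) {
    for (ep in names(x$survival)) {
      s <- x$survival[[ep]]
      if (!is.null(s)) cat(sprintf("  log-rank (%s): chi2 = %.2f, p = %.4g\n",
                                   toupper(ep), s$chi2, s$p))
    }
  }
  invisible(x)
}

report_to_list <- function(report) {
  eval_list <- function(ev) list(
    r2_train = ev$r2_train, r2_test = ev$r2_test,
    se_train = ev$se_train, se_test = ev$se_test,
    acc_exact_train = ev$acc_exact_train, acc_exact_test = ev$acc_exact_test,
    acc_tol1_train = ev$acc_tol1_train, acc_tol1_test = ev$acc_tol1_test,
    truth_train = unname(apply(ev$truth_train$counts, 1, as.list)),
    truth_test = unname(apply(ev$truth_test$counts, 1, as.list)),
    classes = ev$truth_train$classes
  )
  cfg <- report$config
  cfg_echo <- cfg[setdiff(names(cfg), "synthetic")]
  if (!is.null(cfg$synthetic)) cfg_echo$synthetic <- unclass(cfg$synthetic)
  list(
    scenario = report$scenario, n_samples = report$n_samples,
    n_columns = report$n_columns, coding_map = as.list(report$coding_map),
    chosen_beta = report$chosen_beta, beta_rule = report$beta_rule,
    sweep_sizes = report$sweep_sizes,
    selected_features = report$selected_features,
    degenerate = report$degenerate,
    mlr = eval_list(report$mlr_eval), brann = eval_list(report$brann_eval),
    brann_gamma = report$brann_gamma,
    survival = lapply(report$survival, function(s) {
      if (is.null(s)) return(NULL)
      list(chi2 = s$chi2, df = s$df, p = s$p, degenerate = s$degenerate,
           groups = s$groups)
    }),
    seeds = report$seeds, software_version = report$software_version,
    config = cfg_echo
  )
}

#' Write a run report bundle to disk
#'
#' `report.json` (the full report), `coefficients.csv`, and labelled truth
#' tables for both models and partitions. The JSON is a pure function of the
#' configuration and seeds.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write_coefficient_table(report$models$mlr, file.path(dir, "coefficients.csv"))
  write_truth_table(report$mlr_eval$truth_train,
                    file.path(dir, "truth_mlr_train.csv"))
  write_truth_table(report$mlr_eval$truth_test,
                    file.path(dir, "truth_mlr_test.csv"))
  write_truth_table(report$brann_eval$truth_train,
                    file.path(dir, "truth_brann_train.csv"))
  write_truth_table(report$brann_eval$truth_test,
                    file.path(dir, "truth_brann_test.csv"))
  invisible(dir)
}

#' Compare the linear and neural models of one or more runs
#'
#' Paired deltas (BRANN minus MLR-EM) of test/train exact accuracy and
#' r-squared. Given a list of reports (e.g. the same scenario re-run across
#' seeds), also reports the median delta and a 2.5-97.5 percent quantile interval
#' across runs.
#'
#' @param reports a `run_report` or a list of them.
#' @return list with `deltas` (per-run data.frame) and, for multiple runs,
#'   `median` and `interval` rows per metric.
#' @export
compare_models <- function(reports) {
  if (inherits(reports, "run_report")) reports <- list(reports)
  deltas <- do.call(rbind, lapply(reports, function(r) {
    data.frame(
      d_acc_test = r$brann_eval$acc_exact_test - r$mlr_eval$acc_exact_test,
      d_acc_train = r$brann_eval$acc_exact_train - r$mlr_eval$acc_exact_train,
      d_r2_test = r$brann_eval$r2_test - r$mlr_eval$r2_test,
      d_r2_train = r$brann_eval$r2_train - r$mlr_eval$r2_train
    )
  }))
  out <- list(deltas = deltas)
  if (nrow(deltas) > 1) {
    out$median <- vapply(deltas, stats::median, numeric(1))
    out$interval <- vapply(deltas, function(v)
      stats::quantile(v, c(0.025, 0.975), names = FALSE), numeric(2))
    rownames(out$interval) <- c("q2.5", "q97.5")
  }
  out
}
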