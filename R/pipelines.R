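# End-to-end conformalized pipelines: binary transductive, multiclass
# inductive with shift audit, regression inductive.

#' Pipeline configuration
#'
#' Collects everything a pipeline run needs; defaults follow the study
#' design of each task. Split fractions default to 80/0/20 for the
#' transductive binary task (no calibration split) and to train/calibration/
#' test with the calibration set equal to 20% of the training data for the
#' inductive tasks.
#'
#' @param task `"binary_tcp"`, `"multiclass_icp"` or `"regression_icp"`.
#' @param data a [labeled_dataset()], a [generator_spec()] (generated at run
#'   time), or a TSV path for [read_expression_table()].
#' @param external_data optional second cohort (same forms as `data`) for the
#'   multiclass external-validation arm.
#' @param model `"svm"`, `"xgboost"` or `"random_forest"`; defaults to the
#'   task's study model (SVM / XGBoost / random forest respectively).
#' @param measure non-conformity measure; defaults to inverse probability
#'   (binary), hinge (multiclass) or absolute error (regression).
#' @param confidence one or more confidence levels in (0, 1).
#' @param fractions train/calibration/test fractions (see above).
#' @param n_select number of MRMR-selected features (defaults 100/20/10 by
#'   task, capped at the feature count).
#' @param mondrian label-conditional calibration for the inductive classifier.
#' @param log_response regression only: select features against and fit the
#'   point model on the log response (back-transformed predictions), the
#'   appropriate treatment for strictly positive heavy-tailed responses.
#'   Conformal calibration stays on raw absolute residuals either way, so the
#'   intervals remain additive around the prediction. Default `TRUE`.
#' @param tune run the small default hyperparameter grid by 5-fold CV on the
#'   training part.
#' @param n_permutations permutations for the external-cohort MMD audit.
#' @param unclassified_label samples with this label are excluded from
#'   training/calibration and only receive prediction regions (default
#'   `"UNC"`).
#' @param seed master seed; all pipeline randomness derives from it.
#' @param out_dir optional output directory; when set, the run writes a
#'   config echo (JSON), prediction tables (TSV), coverage reports (JSON)
#'   and a log sufficient to re-run identically.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(task, data, external_data = NULL, model = NULL,
                            measure = NULL, confidence = 0.95,
                            fractions = NULL, n_select = NULL,
                            mondrian = FALSE, tune = TRUE,
                            log_response = TRUE,
                            n_permutations = 199,
                            unclassified_label = "UNC",
                            seed = 1L, out_dir = NULL) {
  task <- match.arg(task, c("binary_tcp", "multiclass_icp", "regression_icp"))
  if (length(confidence) < 1 || any(confidence <= 0 | confidence >= 1)) {
    stopf("`confidence` must contain levels strictly between 0 and 1")
  }
  model <- model %||% switch(task, binary_tcp = "svm",
                             multiclass_icp = "xgboost",
                             regression_icp = "random_forest")
  measure <- measure %||% switch(task, binary_tcp = "inverse_probability",
                                 multiclass_icp = "hinge",
                                 regression_icp = "absolute_error")
  fractions <- fractions %||% switch(task,
    binary_tcp = c(0.8, 0, 0.2),
    multiclass_icp = c(0.64, 0.16, 0.2),
    regression_icp = c(0.64, 0.16, 0.2))
  if (task == "binary_tcp" && fractions[2] > 0) {
    stopf("the transductive pipeline takes no calibration fraction")
  }
  n_select <- n_select %||% switch(task, binary_tcp = 100L,
                                   multiclass_icp = 20L, regression_icp = 10L)
  structure(
    list(task = task, data = data, external_data = external_data,
         model = model, measure = measure, confidence = confidence,
         fractions = fractions, n_select = as.integer(n_select),
         mondrian = isTRUE(mondrian), tune = isTRUE(tune),
         log_response = isTRUE(log_response),
         n_permutations = as.integer(n_permutations),
         unclassified_label = unclassified_label,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

resolve_dataset <- function(data) {
  if (inherits(data, "labeled_dataset")) return(data)
  if (inherits(data, "generator_spec")) {
    return(if (is.null(data$class_proportions)) generate_regression(data) else generate_classification(data))
  }
  if (is.character(data) && length(data) == 1) return(read_expression_table(data))
  stopf("`data` must be a labeled_dataset, generator_spec, or file path")
}

config_echo <- function(config) {
  echo <- unclass(config)
  describe <- function(d) {
    if (inherits(d, "labeled_dataset")) {
      list(kind = "dataset", n_samples = length(d$sample_ids),
           n_features = length(d$feature_ids), task = d$task)
    } else if (inherits(d, "generator_spec")) {
      c(list(kind = "generator_spec"), unclass(d))
    } else d
  }
  echo$data <- describe(echo$data)
  if (!is.null(echo$external_data)) echo$external_data <- describe(echo$external_data)
  echo
}

pipeline_outputs <- function(config, files) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config_echo(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (nm in names(files)) files[[nm]]()
  invisible(NULL)
}

select_adapter <- function(config, train, seed) {
  if (config$task == "regression_icp" && config$model == "svm") {
    stopf("svm is not available for the regression task")
  }
  gg <- default_grid(config$model)
  if (config$model == "random_forest") {
    gg$factory <- if (config$task == "regression_icp") {
      function(...) random_forest_adapter(log_target = config$log_response, ...)
    } else {
      function(...) random_forest_adapter(task = "classification", ...)
    }
  }
  if (!config$tune) {
    return(gg$factory())
  }
  tune_grid(gg$factory, gg$grid, train$features, train$labels, seed = seed)$adapter
}

#' Binary transductive conformal pipeline
#'
#' MRMR feature selection on the training split, grid-tuned SVM, transductive
#' conformal regions for every test sample, and a coverage report that scores
#' the conformal layer's error detection against the bare SVM's point
#' predictions. No calibration split is spent — the transductive scheme
#' retrains per candidate label instead, the economical choice for small
#' cohorts.
#'
#' @param config a [pipeline_config()] with `task = "binary_tcp"`.
#' @return list with `report` ([coverage_report()]), `regions`, `base_predictions`,
#'   `base_accuracy`, `selected_features`, `plan`, `adapter`, `config`.
#' @export
run_binary_tcp <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$task != "binary_tcp") stopf("config task is `%s`", config$task)
  dataset <- resolve_dataset(config$data)
  if (dataset$task != "classification" || length(dataset$label_space) != 2) {
    stopf("binary_tcp requires a two-class dataset (got %d classes)",
          length(dataset$label_space %||% character(0)))
  }
  seeds <- derive_seeds(config$seed, 3)
  # The transductive guarantee needs every preprocessing step to treat all
  # n + 1 points symmetrically: feature selection runs on the full cohort
  # before the split (see the methods vignette), unlike the inductive
  # pipelines where train-only selection leaves calibration/test
  # exchangeability intact.
  k <- min(config$n_select, length(dataset$feature_ids))
  selected <- mrmr_select(dataset, k)
  dataset_sel <- subset_dataset(dataset, features = selected)
  plan <- make_split(dataset_sel, config$fractions, stratified = TRUE,
                     seed = seeds[1])
  parts <- split_dataset(dataset_sel, plan)
  train <- parts$train
  test <- parts$test

  adapter <- select_adapter(config, train, seeds[2])
  base_fit <- adapter_fit(adapter, train$features, train$labels,
                          seed = seeds[3], label_space = train$label_space)
  base_pred <- predict_point(base_fit, test$features)

  conf <- as_confidence(config$confidence[1])
  regions <- tcp_predict(train, test$features, adapter,
                         measure = config$measure, conf = conf,
                         seed = seeds[3])
  regions$sample_ids <- test$sample_ids
  report <- coverage_report(regions, test$labels, base_pred)

  result <- list(report = report, regions = regions,
                 base_predictions = base_pred,
                 base_accuracy = mean(base_pred == test$labels),
                 selected_features = selected, plan = plan,
                 adapter = adapter, config = config)
  if (!is.null(config$out_dir)) {
    pipeline_outputs(config, list(
      regions = function() write_prediction_regions(regions, file.path(config$out_dir, "predictions.tsv")),
      report = function() write_coverage_report(report, file.path(config$out_dir, "coverage_report.json")),
      plan = function() write_split_plan(plan, file.path(config$out_dir, "split_plan.json")),
      log = function() writeLines(c(
        sprintf("task: binary_tcp | model: %s | measure: %s", config$model, config$measure),
        sprintf("seed: %d (split %d, tune %d, fit %d)", config$seed, seeds[1], seeds[2], seeds[3]),
        sprintf("selected features: %s", paste(selected, collapse = ",")),
        sprintf("base accuracy: %.6f", result$base_accuracy)
      ), file.path(config$out_dir, "run_log.txt"))
    ))
  }
  result
}

# Split off samples carrying the unclassified label, if any.
split_unclassified <- function(dataset, unc_label) {
  if (dataset$task != "classification" || !(unc_label %in% dataset$labels)) {
    return(list(labeled = dataset, unclassified = NULL))
  }
  unc_idx <- which(dataset$labels == unc_label)
  lab_idx <- setdiff(seq_along(dataset$labels), unc_idx)
  labeled <- labeled_dataset(
    dataset$features[lab_idx, , drop = FALSE], dataset$labels[lab_idx],
    sample_ids = dataset$sample_ids[lab_idx],
    feature_ids = dataset$feature_ids,
    label_space = setdiff(dataset$label_space, unc_label),
    metadata = dataset$metadata)
  unclassified <- subset_dataset(dataset, samples = unc_idx)
  list(labeled = labeled, unclassified = unclassified)
}

#' Multiclass inductive conformal pipeline with shift audit
#'
#' MRMR on the training split, gradient-boosted base model, inductive
#' conformal regions on the internal test split and — when an external
#' cohort is supplied — on the external cohort, plus an MMD permutation test
#' between the two cohorts' selected-feature matrices. Samples labelled with
#' the unclassified category receive prediction regions only and are
#' tabulated separately.
#'
#' @param config a [pipeline_config()] with `task = "multiclass_icp"`.
#' @return list with `report` (internal test [coverage_report()]),
#'   `regions`, `composition`, per-cohort `external` results (report,
#'   regions, composition, `shift_test`), `unclassified` (regions +
#'   composition, or `NULL`), `selected_features`, `plan`, `adapter`,
#'   `config`.
#' @export
run_multiclass_icp <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$task != "multiclass_icp") stopf("config task is `%s`", config$task)
  full <- resolve_dataset(config$data)
  parts0 <- split_unclassified(full, config$unclassified_label)
  dataset <- parts0$labeled
  if (dataset$task != "classification" || length(dataset$label_space) < 3) {
    stopf("multiclass_icp requires at least three classes")
  }
  seeds <- derive_seeds(config$seed, 4)
  plan <- make_split(dataset, config$fractions, stratified = TRUE,
                     seed = seeds[1])
  parts <- split_dataset(dataset, plan)
  k <- min(config$n_select, length(dataset$feature_ids))
  selected <- mrmr_select(parts$train, k)
  train <- subset_dataset(parts$train, features = selected)
  calib <- subset_dataset(parts$calibration, features = selected)
  test <- subset_dataset(parts$test, features = selected)

  adapter <- select_adapter(config, train, seeds[2])
  model <- icp_fit(train, calib, adapter, measure = config$measure,
                   seed = seeds[3])
  conf <- as_confidence(config$confidence[1])
  base_pred <- predict_point(model$fitted, test$features)
  regions <- icp_classify(model, test$features, conf, mondrian = config$mondrian)
  regions$sample_ids <- test$sample_ids
  report <- coverage_report(regions, test$labels, base_pred)

  external <- NULL
  if (!is.null(config$external_data)) {
    ext_full <- resolve_dataset(config$external_data)
    if (!identical(sort(setdiff(ext_full$label_space, config$unclassified_label)),
                   sort(dataset$label_space))) {
      stopf("external cohort label space does not match the training cohort")
    }
    ext <- split_unclassified(ext_full, config$unclassified_label)$labeled
    ext_sel <- subset_dataset(ext, features = selected)
    ext_base <- predict_point(model$fitted, ext_sel$features)
    ext_regions <- icp_classify(model, ext_sel$features, conf,
                                mondrian = config$mondrian)
    ext_regions$sample_ids <- ext_sel$sample_ids
    internal_sel <- subset_dataset(dataset, features = selected)
    shift_test <- mmd_permutation_test(internal_sel$features,
                                       ext_sel$features,
                                       n_permutations = config$n_permutations,
                                       seed = seeds[4])
    external <- list(report = coverage_report(ext_regions, ext_sel$labels, ext_base),
                     regions = ext_regions,
                     composition = region_composition(ext_regions),
                     shift_test = shift_test)
  }

  unclassified <- NULL
  if (!is.null(parts0$unclassified)) {
    unc_sel <- subset_dataset(parts0$unclassified, features = selected)
    unc_regions <- icp_classify(model, unc_sel$features, conf,
                                mondrian = config$mondrian)
    unc_regions$sample_ids <- unc_sel$sample_ids
    unclassified <- list(regions = unc_regions,
                         composition = region_composition(unc_regions))
  }

  result <- list(report = report, regions = regions,
                 composition = region_composition(regions),
                 external = external, unclassified = unclassified,
                 selected_features = selected, plan = plan, adapter = adapter,
                 model = model, config = config)
  if (!is.null(config$out_dir)) {
    pipeline_outputs(config, list(
      regions = function() write_prediction_regions(regions, file.path(config$out_dir, "predictions_internal.tsv")),
      report = function() write_coverage_report(report, file.path(config$out_dir, "coverage_internal.json")),
      plan = function() write_split_plan(plan, file.path(config$out_dir, "split_plan.json")),
      ext = function() if (!is.null(external)) {
        write_prediction_regions(external$regions, file.path(config$out_dir, "predictions_external.tsv"))
        write_coverage_report(external$report, file.path(config$out_dir, "coverage_external.json"))
        write_shift_test(external$shift_test, file.path(config$out_dir, "shift_test.json"))
      },
      unc = function() if (!is.null(unclassified)) {
        write_prediction_regions(unclassified$regions, file.path(config$out_dir, "predictions_unclassified.tsv"))
      },
      log = function() writeLines(c(
        sprintf("task: multiclass_icp | model: %s | measure: %s | mondrian: %s",
                config$model, config$measure, config$mondrian),
        sprintf("seed: %d (split %d, tune %d, fit %d, mmd %d)",
                config$seed, seeds[1], seeds[2], seeds[3], seeds[4]),
        sprintf("selected features: %s", paste(selected, collapse = ","))
      ), file.path(config$out_dir, "run_log.txt"))
    ))
  }
  result
}

#' Regression inductive conformal pipeline
#'
#' Outlier management on the log response, MRMR on the training split, a
#' random-forest point regressor, and symmetric conformal intervals from the
#' absolute-residual calibration quantile at each configured confidence
#' level. The summary lists (confidence, half-width, empirical coverage) per
#' level; half-widths are non-decreasing in confidence because the
#' calibration order statistics nest.
#'
#' @param config a [pipeline_config()] with `task = "regression_icp"`.
#' @return list with `summary` (data.frame: confidence, half_width,
#'   empirical_coverage), `intervals` (list of `prediction_intervals` by
#'   confidence), `mse`, `r_squared`, `removed_ids`, `selected_features`,
#'   `plan`, `adapter`, `config`.
#' @export
run_regression_icp <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$task != "regression_icp") stopf("config task is `%s`", config$task)
  dataset <- resolve_dataset(config$data)
  if (dataset$task != "regression") stopf("regression_icp requires a continuous response")
  filtered <- manage_outliers(dataset)
  removed <- attr(filtered, "removed_ids")
  seeds <- derive_seeds(config$seed, 3)
  plan <- make_split(filtered, config$fractions, stratified = FALSE,
                     seed = seeds[1])
  parts <- split_dataset(filtered, plan)
  k <- min(config$n_select, length(filtered$feature_ids))
  # feature relevance is computed on the modelling scale: a Pearson screen
  # against a heavy-tailed raw response is dominated by the tail
  rank_train <- if (config$log_response) {
    labeled_dataset(parts$train$features, log(parts$train$labels),
                    sample_ids = parts$train$sample_ids,
                    feature_ids = parts$train$feature_ids)
  } else {
    parts$train
  }
  selected <- mrmr_select(rank_train, k)
  train <- subset_dataset(parts$train, features = selected)
  calib <- subset_dataset(parts$calibration, features = selected)
  test <- subset_dataset(parts$test, features = selected)

  adapter <- select_adapter(config, train, seeds[2])
  model <- icp_fit(train, calib, adapter, measure = config$measure,
                   seed = seeds[3])
  point <- predict_point(model$fitted, test$features)
  # point-model fit quality on the modelling scale
  eval_pred <- if (config$log_response) log(pmax(point, 1e-300)) else point
  eval_true <- if (config$log_response) log(test$labels) else test$labels
  mse <- mean((eval_pred - eval_true)^2)
  r2 <- 1 - mse / mean((eval_true - mean(eval_true))^2)

  levels_sorted <- sort(config$confidence)
  intervals <- list()
  summary <- data.frame(confidence = levels_sorted, half_width = NA_real_,
                        empirical_coverage = NA_real_)
  for (i in seq_along(levels_sorted)) {
    ci <- icp_regress_predict(model, test$features, levels_sorted[i])
    ci$sample_id <- test$sample_ids
    intervals[[sprintf("%.2f", levels_sorted[i])]] <- ci
    summary$half_width[i] <- ci$half_width[1]
    summary$empirical_coverage[i] <- empirical_coverage(ci, test$labels)
  }

  result <- list(summary = summary, intervals = intervals, mse = mse,
                 r_squared = r2, removed_ids = removed,
                 selected_features = selected, plan = plan, adapter = adapter,
                 model = model, config = config)
  if (!is.null(config$out_dir)) {
    pipeline_outputs(config, list(
      ints = function() for (nm in names(intervals)) {
        write_prediction_intervals(intervals[[nm]],
          file.path(config$out_dir, sprintf("intervals_%s.tsv", nm)))
      },
      summary = function() jsonlite::write_json(summary,
        file.path(config$out_dir, "coverage_summary.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE),
      plan = function() write_split_plan(plan, file.path(config$out_dir, "split_plan.json")),
      log = function() writeLines(c(
        sprintf("task: regression_icp | model: %s | measure: %s", config$model, config$measure),
        sprintf("seed: %d (split %d, tune %d, fit %d)", config$seed, seeds[1], seeds[2], seeds[3]),
        sprintf("outliers removed: %d", length(removed)),
        sprintf("log-scale modelling: %s", config$log_response),
        sprintf("selected features: %s", paste(selected, collapse = ",")),
        sprintf("test MSE: %.6f | R-squared: %.6f (modelling scale)", mse, r2)
      ), file.path(config$out_dir, "run_log.txt"))
    ))
  }
  result
}
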