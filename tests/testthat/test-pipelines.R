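# Adapters and the three end-to-end pipelines.

test_that("adapters emit valid probability simplices and are seed-deterministic", {
  d <- generate_classification(generator_spec(120, 10, 5,
                                              class_proportions = c(1, 1, 1) / 3,
                                              separation = 2, seed = 51))
  x_new <- d$features[1:7, ]
  adapters <- list(nearest_centroid_adapter(),
                   xgboost_adapter(nrounds = 20),
                   random_forest_adapter(task = "classification", ntree = 80))
  for (ad in adapters) {
    f1 <- adapter_fit(ad, d$features, d$labels, seed = 3)
    f2 <- adapter_fit(ad, d$features, d$labels, seed = 3)
    p1 <- predict_prob(f1, x_new)
    p2 <- predict_prob(f2, x_new)
    expect_identical(p1, p2)
    expect_equal(unname(rowSums(p1)), rep(1, 7), tolerance = 1e-9)
    expect_true(all(p1 >= 0))
    expect_identical(colnames(p1), c("A", "B", "C"))
  }
  # binary svm
  db <- generate_classification(generator_spec(80, 10, 5,
                                               class_proportions = c(0.5, 0.5),
                                               separation = 2, seed = 52))
  fs <- adapter_fit(svm_adapter(), db$features, db$labels, seed = 1)
  ps <- predict_prob(fs, db$features[1:5, ])
  expect_equal(unname(rowSums(ps)), rep(1, 5), tolerance = 1e-9)
  expect_error(adapter_fit(svm_adapter(), d$features, d$labels), "binary")
})

test_that("regression adapters are deterministic under a seed", {
  d <- generate_regression(generator_spec(150, 8, 4, noise_sd = 0.5, seed = 53))
  f1 <- adapter_fit(random_forest_adapter(ntree = 60), d$features, d$labels,
                    seed = 9)
  f2 <- adapter_fit(random_forest_adapter(ntree = 60), d$features, d$labels,
                    seed = 9)
  expect_identical(predict_point(f1, d$features[1:10, ]),
                   predict_point(f2, d$features[1:10, ]))
})

test_that("grid tuning picks deterministically by cross-validation", {
  d <- generate_classification(generator_spec(90, 12, 6,
                                              class_proportions = c(0.5, 0.5),
                                              separation = 1.5, seed = 54))
  t1 <- tune_grid(svm_adapter, data.frame(cost = c(0.1, 1, 10)),
                  d$features, d$labels, seed = 2)
  t2 <- tune_grid(svm_adapter, data.frame(cost = c(0.1, 1, 10)),
                  d$features, d$labels, seed = 2)
  expect_identical(t1$best, t2$best)
  expect_length(t1$scores, 3)
})

test_that("the binary transductive pipeline is valid and reproducible", {
  cfg <- function(dir = NULL) {
    pipeline_config("binary_tcp", spec_infliximab_cohort(seed = 3),
                    n_select = 20, tune = FALSE, seed = 11, out_dir = dir)
  }
  res <- run_binary_tcp(cfg())
  expect_s3_class(res$report, "coverage_report")
  expect_equal(res$report$n_test, 16)
  expect_length(res$selected_features, 20)
  # coverage within binomial reach of the 95% target on 16 samples
  expect_gte(res$report$empirical_coverage, 0.95 - 3 * sqrt(0.05 * 0.95 / 16))
  # byte-identical reruns
  d1 <- tempfile("tcp1"); d2 <- tempfile("tcp2")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  run_binary_tcp(cfg(d1))
  run_binary_tcp(cfg(d2))
  # config.json echoes out_dir, which legitimately differs between runs
  for (f in setdiff(list.files(d1), "config.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_true(all(c("config.json", "predictions.tsv", "coverage_report.json",
                    "split_plan.json", "run_log.txt") %in% list.files(d1)))
})

test_that("binary pipeline rejects non-binary cohorts and calibration fractions", {
  expect_error(pipeline_config("binary_tcp", spec_lymphoma_cohort(),
                               fractions = c(0.6, 0.2, 0.2)),
               "no calibration fraction")
  cfg <- pipeline_config("binary_tcp", spec_lymphoma_cohort(seed = 1),
                         tune = FALSE)
  expect_error(run_binary_tcp(cfg), "two-class")
})

test_that("the multiclass inductive pipeline hedges on the overlapping pair", {
  spec <- generator_spec(700, 60, 15,
                         class_proportions = c(345, 517, 170) / 1032,
                         class_names = c("ABC", "GCB", "MHG"),
                         separation = 1.2, overlap_pair = c(1, 2), seed = 21)
  cfg <- pipeline_config("multiclass_icp", spec, n_select = 15, tune = FALSE,
                         confidence = 0.95, seed = 7)
  res <- run_multiclass_icp(cfg)
  expect_s3_class(res$report, "coverage_report")
  expect_null(res$external)
  comp <- res$composition
  pair_count <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = ",")
    s <- comp$count[comp$region == key]
    if (length(s)) s else 0L
  }
  # doubles concentrate on the overlapping ABC/GCB pair
  expect_gt(pair_count("ABC", "GCB"),
            max(pair_count("ABC", "MHG"), pair_count("GCB", "MHG")))
})

test_that("the multiclass pipeline audits an external shifted cohort", {
  spec <- generator_spec(600, 40, 12,
                         class_proportions = c(1, 1, 1) / 3,
                         class_names = c("ABC", "GCB", "MHG"),
                         separation = 1.5, seed = 22)
  ext <- apply_shift(generate_classification(
    generator_spec(300, 40, 12, class_proportions = c(1, 1, 1) / 3,
                   class_names = c("ABC", "GCB", "MHG"),
                   separation = 1.5, seed = 23)),
    shift_spec(mean_shift = 0.6, fraction_shifted_features = 0.5, seed = 2))
  cfg <- pipeline_config("multiclass_icp", spec, external_data = ext,
                         n_select = 12, tune = FALSE, confidence = 0.95,
                         n_permutations = 99, seed = 9)
  res <- run_multiclass_icp(cfg)
  expect_false(is.null(res$external))
  expect_s3_class(res$external$shift_test, "shift_test_result")
  # a genuine covariate shift is detected
  expect_lte(res$external$shift_test$p_value, 0.05)
  expect_equal(res$external$report$n_test, 300)
})

test_that("unclassified samples get regions but never train the model", {
  d <- generate_classification(generator_spec(300, 20, 8,
                                              class_proportions = c(0.3, 0.3, 0.2, 0.2),
                                              class_names = c("ABC", "GCB", "MHG", "UNC"),
                                              separation = 1.5, seed = 24))
  cfg <- pipeline_config("multiclass_icp", d, n_select = 8, tune = FALSE,
                         seed = 3)
  res <- run_multiclass_icp(cfg)
  expect_false(is.null(res$unclassified))
  n_unc <- sum(d$labels == "UNC")
  expect_length(res$unclassified$regions$region, n_unc)
  expect_identical(res$model$label_space, c("ABC", "GCB", "MHG"))
  expect_false(any(res$unclassified$regions$sample_ids %in%
                     c(res$plan$train_ids, res$plan$calibration_ids)))
})

test_that("the regression pipeline nests half-widths across confidences", {
  spec <- generator_spec(500, 30, 10, noise_sd = 0.5, response_skew = TRUE,
                         response_scale = 1.5, seed = 25)
  cfg <- pipeline_config("regression_icp", spec,
                         confidence = c(0.85, 0.9, 0.95), n_select = 10,
                         model = "random_forest", tune = FALSE, seed = 13)
  res <- run_regression_icp(cfg)
  expect_equal(res$summary$confidence, c(0.85, 0.9, 0.95))
  expect_true(all(diff(res$summary$half_width) >= 0))
  expect_true(all(res$summary$empirical_coverage >= 0.6))
  expect_s3_class(res$intervals[["0.90"]], "prediction_intervals")
})

test_that("pipeline reruns with one config and seed are byte-identical", {
  spec <- generator_spec(260, 20, 6,
                         class_proportions = c(1, 1, 1) / 3,
                         separation = 1.5, seed = 26)
  d1 <- tempfile("icp1"); d2 <- tempfile("icp2")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  for (dir in c(d1, d2)) {
    cfg <- pipeline_config("multiclass_icp", spec, n_select = 6, tune = FALSE,
                           seed = 5, out_dir = dir)
    run_multiclass_icp(cfg)
  }
  for (f in setdiff(list.files(d1), "config.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
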