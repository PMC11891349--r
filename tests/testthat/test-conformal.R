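# Transductive and inductive conformal prediction.

test_that("transductive p-values match the hand-enumerated example", {
  toy <- labeled_dataset(matrix(c(0, 1, 10), ncol = 1), c("A", "A", "B"))
  pr <- tcp_predict(toy, 9, nearest_centroid_adapter(),
                    measure = centroid_distance_measure(), conf = 0.95)
  expect_equal(unname(pr$p_values[1, "B"]), 1.0)
  expect_equal(unname(pr$p_values[1, "A"]), 0.25)
  # confidence 0.95: both labels retained, flagged uncertain
  expect_setequal(pr$region[[1]], c("A", "B"))
  expect_identical(pr$flag[1], "uncertain")
  # confidence 0.70: only B survives (0.25 <= 0.30 < 1.0)
  pr70 <- tcp_predict(toy, 9, nearest_centroid_adapter(),
                      measure = centroid_distance_measure(), conf = 0.70)
  expect_identical(pr70$region[[1]], "B")
  expect_identical(pr70$flag[1], "singleton")
})

test_that("regions obey the p > epsilon rule, including the empty set", {
  pm <- rbind(c(A = 0.9, B = 0.04, C = 0.2),
              c(A = 0.02, B = 0.04, C = 0.05))
  regions <- conformalgx:::new_prediction_regions(pm, 0.95)
  expect_setequal(regions$region[[1]], c("A", "C"))
  expect_identical(regions$region[[2]], character(0))
  expect_true(regions$empty[2])
  expect_identical(regions$flag[2], "uncertain")
  df <- as.data.frame(regions)
  expect_identical(df$region, c("A,C", ""))
  expect_identical(names(df), c("sample_id", "p_A", "p_B", "p_C", "region", "flag"))
})

test_that("icp_fit scores the calibration set with the fitted model", {
  d <- generate_classification(generator_spec(200, 15, 6,
                                              class_proportions = c(0.5, 0.5),
                                              separation = 5, seed = 21))
  parts <- split_dataset(d, make_split(d, c(0.5, 0.25, 0.25), seed = 2))
  m <- icp_fit(parts$train, parts$calibration, nearest_centroid_adapter())
  expect_length(m$scores, n_samples(parts$calibration))
  # widely separable data with a consistent learner: true-class probability
  # above one half everywhere, so all scores below 0.5
  expect_true(all(m$scores < 0.5))
  # refit determinism
  m2 <- icp_fit(parts$train, parts$calibration, nearest_centroid_adapter())
  expect_identical(m$scores, m2$scores)
})

test_that("overlapping train/calibration samples raise a leakage error", {
  d <- generate_classification(generator_spec(40, 10, 4,
                                              class_proportions = c(0.5, 0.5),
                                              seed = 3))
  a <- subset_dataset(d, samples = 1:25)
  b <- subset_dataset(d, samples = 20:40)
  expect_error(icp_fit(a, b, nearest_centroid_adapter()), "leakage")
})

test_that("mondrian p-values rank within the candidate's true-label class", {
  d <- generate_classification(generator_spec(300, 12, 6,
                                              class_proportions = c(0.4, 0.6),
                                              separation = 1.5, seed = 13))
  parts <- split_dataset(d, make_split(d, c(0.4, 0.3, 0.3), seed = 5))
  m <- icp_fit(parts$train, parts$calibration, nearest_centroid_adapter())
  x_test <- parts$test$features[1:8, , drop = FALSE]
  mond <- icp_classify(m, x_test, 0.9, mondrian = TRUE)
  pooled <- icp_classify(m, x_test, 0.9, mondrian = FALSE)
  for (y in m$label_space) {
    s <- conformalgx:::classification_scores(m$fitted, x_test,
                                             rep(y, nrow(x_test)), m$measure)
    expect_equal(unname(mond$p_values[, y]),
                 conformal_p_value(m$scores[m$calibration_labels == y], s))
    expect_equal(unname(pooled$p_values[, y]), conformal_p_value(m$scores, s))
  }
  expect_false(identical(mond$p_values, pooled$p_values))
})

test_that("mondrian calibration demands every class in the calibration set", {
  d <- generate_classification(generator_spec(60, 8, 3,
                                              class_proportions = c(0.5, 0.5),
                                              seed = 14))
  train <- subset_dataset(d, samples = which(d$labels %in% c("A", "B"))[1:30])
  cal_a <- subset_dataset(d, samples = setdiff(which(d$labels == "A"),
                                               match(train$sample_ids, d$sample_ids)))
  m <- icp_fit(train, cal_a, nearest_centroid_adapter())
  expect_error(icp_classify(m, d$features[1:2, ], 0.9, mondrian = TRUE),
               "missing: B")
})

test_that("regions nest across confidence levels", {
  d <- generate_classification(generator_spec(400, 15, 6,
                                              class_proportions = c(1, 1, 1) / 3,
                                              separation = 1.5,
                                              overlap_pair = c(1, 2), seed = 17))
  parts <- split_dataset(d, make_split(d, c(0.4, 0.3, 0.3), seed = 6))
  m <- icp_fit(parts$train, parts$calibration, nearest_centroid_adapter())
  r80 <- icp_classify(m, parts$test$features, 0.80)
  r95 <- icp_classify(m, parts$test$features, 0.95)
  for (i in seq_along(r80$region)) {
    expect_true(all(r80$region[[i]] %in% r95$region[[i]]))
  }
})

test_that("the calibration quantile follows the order-statistic rule", {
  fake_model <- structure(list(scores = 1:9, n_cal = 9L, task = "regression"),
                          class = "calibration_model")
  expect_equal(icp_regress_quantile(fake_model, 0.9), 9)   # k = ceil(10 * .9)
  expect_equal(icp_regress_quantile(fake_model, 0.5), 5)
  small <- structure(list(scores = 1:4, n_cal = 4L, task = "regression"),
                     class = "calibration_model")
  expect_identical(icp_regress_quantile(small, 0.95), Inf)  # k = 5 > n_cal
})

test_that("prediction intervals are symmetric around the point prediction", {
  d <- generate_regression(generator_spec(200, 8, 3, noise_sd = 0.3, seed = 19))
  parts <- split_dataset(d, make_split(d, c(0.5, 0.25, 0.25),
                                       stratified = FALSE, seed = 7))
  m <- icp_fit(parts$train, parts$calibration, linear_adapter())
  ci <- icp_regress_predict(m, parts$test$features, 0.9)
  expect_equal(ci$lower, ci$center - ci$half_width)
  expect_equal(ci$upper, ci$center + ci$half_width)
  expect_equal(ci$upper - ci$lower, rep(2 * ci$half_width[1], nrow(ci)))
  expect_true(all(!ci$unbounded))
  # half-widths nest in confidence
  hw <- vapply(c(0.8, 0.9, 0.95), function(cf) {
    icp_regress_predict(m, parts$test$features, cf)$half_width[1]
  }, 0)
  expect_true(all(diff(hw) >= 0))
})

test_that("interval arithmetic matches the worked half-width example", {
  # a 90% half-width of 6.77 around a prediction of 10
  expect_equal(10 + c(-1, 1) * 6.77, c(3.23, 16.77))
  fake <- structure(list(scores = rep(6.77, 9), n_cal = 9L, task = "regression"),
                    class = "calibration_model")
  expect_equal(icp_regress_quantile(fake, 0.9), 6.77)
})

test_that("a perfect learner on a noiseless response yields degenerate intervals", {
  d <- generate_regression(generator_spec(120, 6, 3, noise_sd = 0, seed = 23))
  parts <- split_dataset(d, make_split(d, c(0.5, 0.25, 0.25),
                                       stratified = FALSE, seed = 8))
  m <- icp_fit(parts$train, parts$calibration, linear_adapter())
  for (cf in c(0.85, 0.9, 0.95)) {
    ci <- icp_regress_predict(m, parts$test$features, cf)
    expect_lt(max(abs(ci$half_width)), 1e-8)
    expect_equal(ci$lower, ci$upper, tolerance = 1e-8)
  }
})

test_that("unbounded intervals carry infinite endpoints", {
  d <- generate_regression(generator_spec(30, 6, 3, noise_sd = 0.5, seed = 29))
  parts <- split_dataset(d, make_split(d, c(0.6, 0.15, 0.25),
                                       stratified = FALSE, seed = 9))
  m <- icp_fit(parts$train, parts$calibration, linear_adapter())
  expect_lt(m$n_cal, 19)  # k exceeds n_cal at 95%
  ci <- icp_regress_predict(m, parts$test$features, 0.95)
  expect_true(all(ci$unbounded))
  expect_true(all(ci$lower == -Inf & ci$upper == Inf))
})

test_that("confidence specification validates and derives epsilon", {
  cs <- confidence_spec(0.9)
  expect_equal(cs$confidence + cs$epsilon, 1)
  expect_error(confidence_spec(1), "strictly between")
  expect_error(confidence_spec(0), "strictly between")
})
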