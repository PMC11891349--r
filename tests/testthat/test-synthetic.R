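# Synthetic cohort generators: reproducibility, planted structure, shifts.

test_that("identical spec and seed reproduce a dataset bit-for-bit", {
  spec <- generator_spec(60, 25, 8, class_proportions = c(0.4, 0.6), seed = 31)
  d1 <- generate_classification(spec)
  d2 <- generate_classification(spec)
  expect_identical(d1$features, d2$features)
  expect_identical(d1$labels, d2$labels)

  rspec <- generator_spec(60, 25, 8, response_skew = TRUE, seed = 31)
  r1 <- generate_regression(rspec)
  r2 <- generate_regression(rspec)
  expect_identical(r1$features, r2$features)
  expect_identical(r1$labels, r2$labels)

  # a different seed changes the draw
  d3 <- generate_classification(generator_spec(60, 25, 8,
                                               class_proportions = c(0.4, 0.6),
                                               seed = 32))
  expect_false(identical(d1$features, d3$features))
})

test_that("class counts follow the proportions up to rounding", {
  spec <- generator_spec(101, 10, 3, class_proportions = c(0.5, 0.3, 0.2),
                         seed = 4)
  d <- generate_classification(spec)
  counts <- table(factor(d$labels, levels = c("A", "B", "C")))
  expect_equal(sum(counts), 101)
  expect_true(all(abs(counts - 101 * c(0.5, 0.3, 0.2)) <= 1))
})

test_that("zero separation carries no class signal", {
  spec <- generator_spec(400, 30, 10, class_proportions = c(0.5, 0.5),
                         separation = 0, seed = 2)
  d <- generate_classification(spec)
  plan <- make_split(d, c(0.7, 0, 0.3), seed = 1)
  parts <- split_dataset(d, plan)
  fit <- adapter_fit(nearest_centroid_adapter(), parts$train$features,
                     parts$train$labels)
  acc <- mean(predict_point(fit, parts$test$features) == parts$test$labels)
  expect_gt(acc, 0.33)
  expect_lt(acc, 0.67)
})

test_that("the overlap pair sits closer than the separable class", {
  spec <- generator_spec(600, 30, 12, class_proportions = c(1, 1, 1) / 3,
                         separation = 3, overlap_pair = c(2, 3), seed = 7)
  d <- generate_classification(spec)
  inf <- d$metadata$informative
  centroid <- function(cl) colMeans(d$features[d$labels == cl, inf])
  d_bc <- sqrt(sum((centroid("B") - centroid("C"))^2))
  d_ab <- sqrt(sum((centroid("A") - centroid("B"))^2))
  d_ac <- sqrt(sum((centroid("A") - centroid("C"))^2))
  expect_lt(d_bc, d_ab)
  expect_lt(d_bc, d_ac)
})

test_that("held-out accuracy increases with separation", {
  acc_at <- function(sep) {
    mean(vapply(1:3, function(s) {
      d <- generate_classification(
        generator_spec(300, 20, 8, class_proportions = c(0.5, 0.5),
                       separation = sep, seed = s))
      plan <- make_split(d, c(0.7, 0, 0.3), seed = s)
      parts <- split_dataset(d, plan)
      fit <- adapter_fit(nearest_centroid_adapter(), parts$train$features,
                         parts$train$labels)
      mean(predict_point(fit, parts$test$features) == parts$test$labels)
    }, 0))
  }
  accs <- vapply(c(0.5, 1.5, 3), acc_at, 0)
  expect_true(all(diff(accs) > 0))
})

test_that("noiseless single-feature linear response equals the feature", {
  spec <- generator_spec(40, 5, 1, noise_sd = 0, seed = 9)
  d <- generate_regression(spec)
  expect_equal(d$labels, unname(d$features[, 1]))
})

test_that("skewed responses are strictly positive and right-skewed", {
  spec <- generator_spec(800, 10, 4, noise_sd = 0.5, response_skew = TRUE,
                         response_scale = 1.9, seed = 11)
  d <- generate_regression(spec)
  expect_true(all(d$labels > 0))
  expect_gt(sample_skewness(d$labels), 0)
})

test_that("ic50 preset spans several orders of magnitude", {
  d <- generate_regression(spec_ic50_cohort(seed = 3))
  expect_gt(log10(max(d$labels) / min(d$labels)), 4)
})

test_that("null shift is the identity map and labels never change", {
  d <- generate_classification(generator_spec(50, 12, 4,
                                              class_proportions = c(0.5, 0.5),
                                              seed = 5))
  same <- apply_shift(d, shift_spec(mean_shift = 0, scale_factor = 1))
  expect_identical(same$features, d$features)
  expect_identical(same$labels, d$labels)

  shifted <- apply_shift(d, shift_spec(mean_shift = 2, scale_factor = 1.5,
                                       fraction_shifted_features = 0.5,
                                       seed = 3))
  expect_identical(shifted$labels, d$labels)
  expect_false(identical(shifted$features, d$features))
  # deterministic under the shift seed
  shifted2 <- apply_shift(d, shift_spec(mean_shift = 2, scale_factor = 1.5,
                                        fraction_shifted_features = 0.5,
                                        seed = 3))
  expect_identical(shifted$features, shifted2$features)
})

test_that("a strong full-feature shift is detected at the minimal p-value", {
  d <- generate_classification(generator_spec(60, 10, 4,
                                              class_proportions = c(0.5, 0.5),
                                              seed = 6))
  shifted <- apply_shift(d, shift_spec(mean_shift = 6))
  res <- mmd_permutation_test(d$features, shifted$features,
                              n_permutations = 99, seed = 1)
  expect_equal(res$p_value, 1 / 100)
})

test_that("invalid specifications are rejected", {
  expect_error(generator_spec(10, 5, 8, class_proportions = c(0.5, 0.5)),
               "n_informative")
  expect_error(generator_spec(10, 5, 2, class_proportions = c(0.5, 0.6)),
               "sum to 1")
  expect_error(generator_spec(10, 5, 2, class_proportions = c(0.5, 0.5),
                              overlap_pair = c(1, 3)), "overlap_pair")
  expect_error(generator_spec(10, 5, 2, overlap_pair = c(1, 2)),
               "class_proportions")
  expect_error(shift_spec(fraction_shifted_features = 1.2), "0, 1")
  expect_error(generate_regression(
    generator_spec(10, 5, 2, class_proportions = c(0.5, 0.5))),
    "class_proportions")
})

test_that("datasets round-trip through the TSV + sidecar writer", {
  d <- generate_classification(generator_spec(20, 6, 2,
                                              class_proportions = c(0.5, 0.5),
                                              seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(d, path)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(unlist(meta$informative), d$metadata$informative)
  back <- read_expression_table(path)
  expect_identical(back$features, d$features)
  expect_identical(back$labels, d$labels)
})
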