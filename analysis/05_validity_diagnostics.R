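#!/usr/bin/env Rscript
# Distribution-level diagnostics of the conformal machinery itself:
# repeated-split coverage against the calibration-size Beta law, true-label
# p-value super-uniformity, MMD test calibration (type-I error) and power,
# and uncertainty inflation along a covariate-shift grid.

library(conformalgx)

seed <- 20260101L
dir.create("results/diagnostics", recursive = TRUE, showWarnings = FALSE)

## 1. repeated-split coverage, confidence 0.90, splits 600/200/1000
d <- generate_classification(
  generator_spec(1800, 20, 10, class_proportions = c(1, 1, 1) / 3,
                 separation = 1.5, overlap_pair = c(1, 2), seed = seed))
cov <- repeated_split_coverage(d, nearest_centroid_adapter(), conf = 0.9,
                               n_repeats = 100, seed = seed,
                               fractions = c(600, 200, 1000) / 1800)
beta_a <- 181; beta_b <- 20  # Beta(n_cal + 1 - l, l), l = floor(eps (n_cal+1))
cat(sprintf("repeated-split coverage: mean %.4f (Beta law mean %.4f), sd %.4f, min %.3f\n",
            mean(cov), beta_a / (beta_a + beta_b), sd(cov), min(cov)))
cat(sprintf("fraction of repeats >= 0.87: %.2f (Beta law predicts %.2f)\n",
            mean(cov >= 0.87), 1 - pbeta(0.87, beta_a, beta_b)))

## 2. super-uniformity of true-label p-values
pooled <- unlist(lapply(1:5, function(s) {
  dd <- generate_classification(
    generator_spec(3500, 20, 10, class_proportions = c(1, 1, 1) / 3,
                   separation = 1.5, overlap_pair = c(1, 2), seed = seed + s))
  parts <- split_dataset(dd, make_split(dd, c(500, 2000, 1000) / 3500,
                                        seed = seed + s))
  m <- icp_fit(parts$train, parts$calibration, nearest_centroid_adapter(),
               seed = seed + s)
  r <- icp_classify(m, parts$test$features, 0.9)
  r$p_values[cbind(seq_along(parts$test$labels),
                   match(parts$test$labels, m$label_space))]
}))
cat("\ntrue-label p-value ECDF (super-uniform if <= t):\n")
for (t in c(0.05, 0.1, 0.2, 0.5)) {
  cat(sprintf("  t = %.2f: ECDF %.4f\n", t, mean(pooled <= t)))
}

## 3. MMD calibration and power
type1 <- mean(vapply(1:200, function(s) {
  x <- conformalgx:::with_seed(seed + s, matrix(rnorm(30 * 5), ncol = 5))
  y <- conformalgx:::with_seed(seed + 5000 + s, matrix(rnorm(30 * 5), ncol = 5))
  mmd_permutation_test(x, y, n_permutations = 199, seed = s)$p_value <= 0.05
}, NA))
power5 <- mean(vapply(1:20, function(s) {
  x <- conformalgx:::with_seed(seed + s, matrix(rnorm(30 * 5), ncol = 5))
  y <- conformalgx:::with_seed(seed + 9000 + s,
                               matrix(rnorm(30 * 5, mean = 5), ncol = 5))
  mmd_permutation_test(x, y, n_permutations = 199, seed = s)$p_value <= 0.05
}, NA))
cat(sprintf("\nMMD permutation test: type-I error %.3f at alpha 0.05; power %.2f at a 5-SD shift\n",
            type1, power5))

## 4. uncertainty inflation along a covariate-shift grid (distance measure)
unc_at <- function(mshift, s) {
  spec <- generator_spec(1400, 50, 15, class_proportions = c(1, 1, 1) / 3,
                         separation = 2, seed = s)
  dd <- generate_classification(spec)
  parts <- split_dataset(dd, make_split(dd, c(0.43, 0.14, 0.43), seed = s))
  m <- icp_fit(parts$train, parts$calibration, nearest_centroid_adapter(),
               measure = centroid_distance_measure(), seed = s)
  ext <- apply_shift(parts$test,
                     shift_spec(mean_shift = mshift,
                                fraction_shifted_features = 0.5, seed = s))
  unc_rate(icp_classify(m, ext$features, 0.95))
}
cat("\nUNC rate vs shift magnitude (centroid-distance measure, mean over 5 seeds):\n")
grid <- c(0, 0.5, 1)
unc <- vapply(grid, function(mm) mean(vapply(1:5, function(s) unc_at(mm, s), 0)), 0)
for (i in seq_along(grid)) {
  cat(sprintf("  mean shift %.1f SD: UNC rate %.3f\n", grid[i], unc[i]))
}

out <- list(repeated_split = list(mean = mean(cov), sd = sd(cov),
                                  frac_ge_087 = mean(cov >= 0.87)),
            p_value_ecdf = as.list(stats::setNames(
              vapply(c(0.05, 0.1, 0.2, 0.5), function(t) mean(pooled <= t), 0),
              c("t05", "t10", "t20", "t50"))),
            mmd = list(type1 = type1, power_5sd = power5),
            shift_unc = as.list(stats::setNames(unc, sprintf("shift_%g", grid))))
jsonlite::write_json(out, "results/diagnostics/validity.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nwrote results/diagnostics/validity.json\n")
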