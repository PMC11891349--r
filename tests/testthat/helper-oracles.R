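# Independent oracles and small fixture builders shared across tests.

# Brute-force transductive conformal p-values with the distance-to-own-class-
# mean non-conformity, written with naive loops and no package internals.
brute_force_tcp <- function(x, y, x_new, label_space) {
  n <- nrow(x)
  p_out <- stats::setNames(numeric(length(label_space)), label_space)
  for (cand in label_space) {
    xa <- rbind(x, matrix(x_new, nrow = 1))
    ya <- c(y, cand)
    means <- list()
    for (cl in unique(ya)) {
      rows <- which(ya == cl)
      acc <- rep(0, ncol(xa))
      for (r in rows) acc <- acc + xa[r, ]
      means[[cl]] <- acc / length(rows)
    }
    alpha <- numeric(n + 1)
    for (i in seq_len(n + 1)) {
      dv <- xa[i, ] - means[[ya[i]]]
      alpha[i] <- sqrt(sum(dv * dv))
    }
    p_out[cand] <- sum(alpha >= alpha[n + 1]) / (n + 1)
  }
  p_out
}

# Naive O(n^2) double-loop squared-MMD V-statistic with a Gaussian kernel.
naive_mmd <- function(x, y, h) {
  kern <- function(a, b) exp(-sum((a - b)^2) / (2 * h^2))
  avg <- function(a, b) {
    s <- 0
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      s <- s + kern(a[i, ], b[j, ])
    }
    s / (nrow(a) * nrow(b))
  }
  avg(x, x) + avg(y, y) - 2 * avg(x, y)
}

# Seed-scoped evaluation (restores the caller's RNG state).
with_seed_local <- function(seed, code) conformalgx:::with_seed(seed, code)

# Sample skewness (method-of-moments).
sample_skewness <- function(v) {
  m <- mean(v)
  mean((v - m)^3) / mean((v - m)^2)^1.5
}

# Prefix sample ids so two generated datasets can serve as disjoint cohorts.
relabel_samples <- function(dataset, prefix) {
  ids <- paste0(prefix, dataset$sample_ids)
  labeled_dataset(dataset$features, dataset$labels, sample_ids = ids,
                  feature_ids = dataset$feature_ids,
                  label_space = dataset$label_space,
                  metadata = dataset$metadata)
}

# A small three-part split of one generated classification dataset.
make_icp_parts <- function(spec, fractions, seed = 1L) {
  d <- generate_classification(spec)
  plan <- make_split(d, fractions, seed = seed)
  split_dataset(d, plan)
}
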