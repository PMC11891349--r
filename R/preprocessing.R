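# Preprocessing: MRMR feature selection, response outlier management,
# seeded splitting, exchangeability diagnostic.

# Vectorized one-way ANOVA F statistics of each feature against a
# categorical response. Constant features get relevance 0.
feature_f_stats <- function(x, y) {
  y <- as.factor(y)
  n <- nrow(x)
  k <- nlevels(y)
  grand <- colMeans(x)
  ssb <- numeric(ncol(x))
  ssw <- numeric(ncol(x))
  for (lv in levels(y)) {
    xi <- x[y == lv, , drop = FALSE]
    mi <- colMeans(xi)
    ssb <- ssb + nrow(xi) * (mi - grand)^2
    ssw <- ssw + colSums(sweep(xi, 2, mi)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[!is.finite(f)] <- 0
  f
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy MRMR with the difference criterion: the first feature maximizes
#' relevance to the response (one-way ANOVA F statistic for categorical
#' labels, absolute Pearson correlation for continuous responses); each
#' subsequent pick maximizes `relevance - mean(|cor(feature, selected)|)`.
#' Features with zero relevance (constant features included) are only
#' eligible once every positive-relevance feature has been taken, so a
#' constant feature can never precede an informative one.
#'
#' @param dataset a [labeled_dataset()].
#' @param k number of features to select (`<= n_features`).
#' @return character vector of `k` feature ids in selection order, with the
#'   per-feature relevance attached as attribute `relevance`.
#' @export
mrmr_select <- function(dataset, k) {
  x <- dataset$features
  p <- ncol(x)
  if (k < 1 || k > p) stopf("`k` must lie in 1..%d", p)
  relevance <- if (dataset$task == "classification") {
    feature_f_stats(x, dataset$labels)
  } else {
    sds <- apply(x, 2, stats::sd)
    r <- rep(0, p)
    ok <- sds > 0
    if (stats::sd(dataset$labels) > 0) {
      r[ok] <- abs(stats::cor(x[, ok, drop = FALSE], dataset$labels))
    }
    r
  }
  names(relevance) <- dataset$feature_ids

  selected <- integer(0)
  red_sum <- rep(0, p)
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    score <- if (length(selected) == 0) {
      relevance[remaining]
    } else {
      relevance[remaining] - red_sum[remaining] / length(selected)
    }
    pos <- relevance[remaining] > 0
    pick <- if (any(pos)) {
      remaining[pos][which.max(score[pos])]
    } else {
      remaining[which.max(score)]
    }
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) && step < k) {
      sd_pick <- stats::sd(x[, pick])
      rho <- if (sd_pick > 0) {
        sds <- apply(x[, remaining, drop = FALSE], 2, stats::sd)
        r <- rep(0, length(remaining))
        ok <- sds > 0
        if (any(ok)) {
          r[ok] <- abs(stats::cor(x[, remaining[ok], drop = FALSE], x[, pick]))
        }
        r
      } else {
        rep(0, length(remaining))
      }
      red_sum[remaining] <- red_sum[remaining] + rho
    }
  }
  out <- dataset$feature_ids[selected]
  attr(out, "relevance") <- relevance[selected]
  out
}

#' Remove gross response outliers (regression)
#'
#' Removes samples whose log-response lies more than `multiplier` times the
#' interquartile range beyond the quartiles of the log-response distribution
#' — a conservative fence suited to heavy-tailed, strictly positive
#' responses such as IC50. Removed sample ids are attached as attribute
#' `removed_ids`.
#'
#' @param dataset regression [labeled_dataset()] with positive responses.
#' @param multiplier IQR multiplier (default 3).
#' @return the filtered dataset, with attribute `removed_ids`.
#' @export
manage_outliers <- function(dataset, multiplier = 3) {
  if (dataset$task != "regression") stopf("manage_outliers requires a regression dataset")
  if (any(dataset$labels <= 0)) {
    stopf("log-scale outlier management requires strictly positive responses")
  }
  ly <- log(dataset$labels)
  q <- stats::quantile(ly, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  keep <- ly >= q[1] - multiplier * iqr & ly <= q[2] + multiplier * iqr
  out <- subset_dataset(dataset, samples = which(keep))
  attr(out, "removed_ids") <- dataset$sample_ids[!keep]
  out
}

#' Seeded train/calibration/test split
#'
#' Partitions the sample ids into train, calibration and test parts by the
#' given fractions (largest-remainder rounding, so parts are within one
#' sample of the exact proportions). Stratified splits apply the allocation
#' within each class, preserving class proportions to within one sample per
#' class. A zero calibration fraction yields the transductive layout.
#'
#' @param dataset a [labeled_dataset()].
#' @param fractions length-3 numeric `(train, calibration, test)` summing to 1.
#' @param stratified stratify by class (classification only).
#' @param seed split seed.
#' @return object of class `split_plan` with `train_ids`, `calibration_ids`,
#'   `test_ids`, `fractions`, `stratified`, `seed`.
#' @export
make_split <- function(dataset, fractions = c(0.6, 0.2, 0.2),
                       stratified = dataset$task == "classification",
                       seed = 1L) {
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stopf("`fractions` must be three non-negative numbers summing to 1")
  }
  if (stratified && dataset$task != "classification") {
    stopf("stratified splits require a classification dataset")
  }
  n_parts <- sum(fractions > 0)
  ids <- dataset$sample_ids
  assign_part <- function(ids_grp) {
    counts <- allocate_counts(length(ids_grp), fractions)
    shuffled <- sample(ids_grp)
    split(shuffled, rep(c("train", "calibration", "test"), counts))
  }
  parts <- with_seed(seed, {
    if (stratified) {
      acc <- list(train = character(0), calibration = character(0),
                  test = character(0))
      for (cl in dataset$label_space) {
        grp <- ids[dataset$labels == cl]
        if (length(grp) < n_parts) {
          stopf("class `%s` has %d sample(s), fewer than the %d split parts",
                cl, length(grp), n_parts)
        }
        pp <- assign_part(grp)
        for (nm in names(pp)) acc[[nm]] <- c(acc[[nm]], pp[[nm]])
      }
      acc
    } else {
      if (length(ids) < n_parts) stopf("dataset too small to split")
      assign_part(ids)
    }
  })
  # restore dataset order within each part for reproducible downstream output
  reorder <- function(v) v[order(match(v, ids))]
  structure(
    list(train_ids = reorder(parts$train %||% character(0)),
         calibration_ids = reorder(parts$calibration %||% character(0)),
         test_ids = reorder(parts$test %||% character(0)),
         fractions = fractions, stratified = stratified,
         seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train %d | calibration %d | test %d (seed %d%s)\n",
              length(x$train_ids), length(x$calibration_ids),
              length(x$test_ids), x$seed,
              if (x$stratified) ", stratified" else ""))
  invisible(x)
}

#' Materialize a split plan
#'
#' @param dataset a [labeled_dataset()].
#' @param plan a [make_split()] result.
#' @return list with `train`, `calibration` (`NULL` when empty) and `test`
#'   datasets.
#' @export
split_dataset <- function(dataset, plan) {
  part <- function(ids) if (length(ids)) subset_dataset(dataset, samples = ids) else NULL
  list(train = part(plan$train_ids),
       calibration = part(plan$calibration_ids),
       test = part(plan$test_ids))
}

#' Serialize a split plan as JSON
#'
#' @param plan a `split_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Exchangeability diagnostic
#'
#' Checks the i.i.d./exchangeability assumption that conformal validity
#' rests on, by MMD-testing random halves of the dataset against each other
#' and reporting the median permutation p-value (large = no evidence against
#' exchangeability). `split = "sequential"` instead tests the first half of
#' the samples against the second half in file order, which is sensitive to
#' order-dependent structure (e.g. two concatenated cohorts) that random
#' halves would mix away.
#'
#' @param dataset a [labeled_dataset()].
#' @param n_splits number of random-half repeats (ignored for sequential).
#' @param seed master seed.
#' @param n_permutations permutations per MMD test.
#' @param split `"random"` (default) or `"sequential"`.
#' @return median p-value, with the per-split p-values attached as attribute
#'   `p_values`.
#' @export
exchangeability_check <- function(dataset, n_splits = 10, seed = 1L,
                                  n_permutations = 99,
                                  split = c("random", "sequential")) {
  split <- match.arg(split)
  n <- n_samples(dataset)
  if (n < 4) stopf("dataset too small for an exchangeability check")
  if (n_splits < 1) stopf("`n_splits` must be at least 1")
  x <- dataset$features
  if (split == "sequential") {
    half <- floor(n / 2)
    res <- mmd_permutation_test(x[seq_len(half), , drop = FALSE],
                                x[seq(half + 1, n), , drop = FALSE],
                                n_permutations = n_permutations, seed = seed)
    p <- res$p_value
    attr(p, "p_values") <- res$p_value
    return(p)
  }
  seeds <- derive_seeds(seed, n_splits)
  ps <- vapply(seq_len(n_splits), function(i) {
    idx <- with_seed(seeds[i], sample.int(n, floor(n / 2)))
    mmd_permutation_test(x[idx, , drop = FALSE], x[-idx, , drop = FALSE],
                         n_permutations = n_permutations,
                         seed = seeds[i])$p_value
  }, 0)
  p <- stats::median(ps)
  attr(p, "p_values") <- ps
  p
}
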