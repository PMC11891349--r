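# Distribution-shift detection between cohorts: kernel two-sample testing
# via the maximum mean discrepancy (MMD) with a permutation null.

#' Median-heuristic kernel bandwidth
#'
#' Median of the pairwise Euclidean distances over the pooled sample, the
#' standard default bandwidth for a Gaussian kernel. Falls back to 1 when all
#' pooled points coincide (median distance 0).
#'
#' @param x,y numeric matrices with matching feature columns (`y` optional).
#' @return positive bandwidth.
#' @export
median_heuristic_bandwidth <- function(x, y = NULL) {
  z <- rbind(as.matrix(x), if (!is.null(y)) as.matrix(y))
  if (nrow(z) < 2) stopf("need at least two pooled samples")
  med <- stats::median(stats::dist(z))
  if (med <= 0) 1 else med
}

# Squared Euclidean cross-distances, clipped at 0 for rounding noise.
pairwise_sqdist <- function(z) {
  g <- z %*% t(z)
  d2 <- outer(diag(g), diag(g), "+") - 2 * g
  d2[d2 < 0] <- 0
  d2
}

# Squared-MMD V-statistic from a pooled kernel matrix and a 0/1 group
# indicator (1 = first sample). O(N^2) via one matrix-vector product.
mmd_from_kernel <- function(kmat, ind) {
  n <- sum(ind)
  m <- length(ind) - n
  kz <- as.numeric(kmat %*% ind)
  sxx <- sum(ind * kz)
  sxy <- sum((1 - ind) * kz)
  syy <- sum(kmat) - sxx - 2 * sxy
  sxx / n^2 + syy / m^2 - 2 * sxy / (n * m)
}

#' Squared maximum mean discrepancy (biased V-statistic)
#'
#' Gaussian-kernel squared MMD between two samples,
#' `mean(Kxx) + mean(Kyy) - 2 mean(Kxy)` with
#' `k(a, b) = exp(-||a - b||^2 / (2 bandwidth^2))`. The biased (V-statistic)
#' form is non-negative and symmetric in its arguments; the permutation null
#' used by [mmd_permutation_test()] makes the estimator choice immaterial for
#' the test's validity.
#'
#' @param x,y numeric matrices with the same number of columns.
#' @param bandwidth Gaussian kernel bandwidth; default is the median
#'   heuristic on the pooled sample.
#' @return squared MMD, `>= 0`.
#' @export
mmd_statistic <- function(x, y, bandwidth = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) == 0 || nrow(y) == 0) stopf("both samples must be non-empty")
  if (ncol(x) != ncol(y)) {
    stopf("feature mismatch: x has %d columns, y has %d", ncol(x), ncol(y))
  }
  bandwidth <- bandwidth %||% median_heuristic_bandwidth(x, y)
  z <- rbind(x, y)
  kmat <- exp(-pairwise_sqdist(z) / (2 * bandwidth^2))
  ind <- c(rep(1, nrow(x)), rep(0, nrow(y)))
  max(mmd_from_kernel(kmat, ind), 0)
}

#' MMD permutation two-sample test
#'
#' Tests whether two cohorts are drawn from the same distribution. The
#' bandwidth is fixed from the pooled sample (it is permutation-invariant,
#' keeping the test exact), the pooled kernel matrix is computed once, and
#' each permutation reshuffles the pooled rows into groups of the original
#' sizes. The p-value carries the +1 correction,
#' `p = (1 + #\{MMD_perm >= MMD_obs\}) / (B + 1)`, so its minimum is
#' `1/(B + 1)`.
#'
#' @param x,y numeric matrices with the same feature columns.
#' @param n_permutations number of permutations `B`.
#' @param seed permutation seed.
#' @param bandwidth optional fixed bandwidth (default: median heuristic).
#' @return object of class `shift_test_result` with fields `mmd`, `p_value`,
#'   `n_permutations`, `bandwidth`, `seed`, `n_x`, `n_y`.
#' @export
mmd_permutation_test <- function(x, y, n_permutations = 199, seed = 1L,
                                 bandwidth = NULL) {
  if (n_permutations < 1) stopf("`n_permutations` must be at least 1")
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) == 0 || nrow(y) == 0) stopf("both samples must be non-empty")
  if (ncol(x) != ncol(y)) {
    stopf("feature mismatch: x has %d columns, y has %d", ncol(x), ncol(y))
  }
  bandwidth <- bandwidth %||% median_heuristic_bandwidth(x, y)
  z <- rbind(x, y)
  kmat <- exp(-pairwise_sqdist(z) / (2 * bandwidth^2))
  n <- nrow(x)
  total <- nrow(z)
  ind <- c(rep(1, n), rep(0, total - n))
  observed <- max(mmd_from_kernel(kmat, ind), 0)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      pi <- numeric(total)
      pi[sample.int(total, n)] <- 1
      mmd_from_kernel(kmat, pi)
    }, 0)
  })
  p <- (1 + sum(perm_stats >= observed)) / (n_permutations + 1)
  structure(
    list(mmd = observed, p_value = p, n_permutations = as.integer(n_permutations),
         bandwidth = bandwidth, seed = as.integer(seed),
         n_x = nrow(x), n_y = nrow(y)),
    class = "shift_test_result"
  )
}

#' @export
print.shift_test_result <- function(x, ...) {
  cat(sprintf("<shift_test_result> MMD^2 = %.4g, p = %.4g (B = %d, bandwidth = %.4g)\n",
              x$mmd, x$p_value, x$n_permutations, x$bandwidth))
  invisible(x)
}

#' Serialize a shift test result as JSON
#'
#' @param result a `shift_test_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shift_test <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
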