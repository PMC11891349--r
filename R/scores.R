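#' Non-conformity measures
#'
#' A non-conformity score quantifies how strange an instance looks relative
#' to a model's predictions; larger means stranger. The package ships the
#' three measures used by its pipelines:
#'
#' * `inverse_probability_score()`: `1 - p(y | x)`, one minus the predicted
#'   probability of the considered label.
#' * `hinge_score()`: the convention adopted for the "hinge" measure in
#'   standard conformal implementations, numerically identical to the
#'   inverse probability, `1 - p(y | x)`.
#' * `absolute_error_score()`: `|y - yhat|`, the absolute deviation of a
#'   point prediction from the observed response (regression).
#'
#' @param prob_vector named probability vector over the label space (or a
#'   plain vector with `label_space` supplied).
#' @param label the label whose score is requested.
#' @param label_space label names when `prob_vector` is unnamed.
#' @return a score in `[0, 1]` (classification measures) or `>= 0`
#'   (absolute error).
#' @examples
#' inverse_probability_score(c(A = 0.7, B = 0.3), "A") # 0.3
#' hinge_score(c(A = 0.9, B = 0.05, C = 0.05), "B")    # 0.95
#' absolute_error_score(5, 3)                          # 2
#' @export
inverse_probability_score <- function(prob_vector, label, label_space = NULL) {
  label_space <- label_space %||% names(prob_vector)
  if (is.null(label_space)) stopf("`prob_vector` must be named or `label_space` given")
  idx <- match(label, label_space)
  if (anyNA(idx)) stopf("label `%s` is not in the label space", label[which(is.na(idx))[1]])
  as.numeric(1 - prob_vector[idx])
}

#' @rdname inverse_probability_score
#' @export
hinge_score <- function(prob_vector, label, label_space = NULL) {
  inverse_probability_score(prob_vector, label, label_space)
}

#' @rdname inverse_probability_score
#' @param y_true observed response.
#' @param y_pred predicted response.
#' @export
absolute_error_score <- function(y_true, y_pred) {
  if (any(!is.finite(y_true)) || any(!is.finite(y_pred))) {
    stopf("absolute_error_score requires finite inputs")
  }
  abs(y_true - y_pred)
}

#' Conformal p-value of a test score against reference scores
#'
#' The rank-based tail probability with the finite-sample +1 correction:
#' `(#\{alpha_i >= alpha\} + 1) / (n + 1)`, ties counted as `>=`. Values lie
#' in `[1/(n+1), 1]`. This is the non-smoothed (deterministic) p-value; see
#' the methods vignette for the smoothed variant trade-off.
#'
#' @param reference_scores non-empty numeric vector of calibration scores.
#' @param test_score numeric scalar or vector of test scores.
#' @return p-values, one per test score.
#' @examples
#' conformal_p_value(c(0.1, 0.2, 0.3, 0.4), 0.25) # (2 + 1) / 5 = 0.6
#' @export
conformal_p_value <- function(reference_scores, test_score) {
  if (length(reference_scores) == 0) stopf("reference score set is empty")
  if (anyNA(reference_scores) || anyNA(test_score)) stopf("scores must not be missing")
  n <- length(reference_scores)
  sorted <- sort(reference_scores)
  # #\{ref >= t\} via binary search on the sorted reference scores
  ge <- n - findInterval(test_score, sorted, left.open = TRUE)
  (ge + 1) / (n + 1)
}

# Non-conformity scores for (features, label) pairs under a fitted adapter.
# `measure` is either a built-in name ("inverse_probability"/"hinge") or a
# function(fitted, x, labels) -> numeric scores.
classification_scores <- function(fitted, x, labels, measure) {
  if (is.function(measure)) return(as.numeric(measure(fitted, x, labels)))
  measure <- match.arg(measure, c("inverse_probability", "hinge"))
  pr <- predict_prob(fitted, x)
  idx <- match(labels, fitted$label_space)
  if (anyNA(idx)) stopf("labels outside the fitted label space")
  as.numeric(1 - pr[cbind(seq_len(nrow(pr)), idx)])
}

#' Distance-to-own-class-mean non-conformity measure
#'
#' A deterministic measure for use with [nearest_centroid_adapter()]: the
#' non-conformity of `(x, y)` is the Euclidean distance from `x` to the
#' fitted centroid of class `y`. Because it is closed-form it supports exact
#' brute-force verification of transductive predictions on small datasets.
#'
#' @return a measure function suitable for [tcp_predict()] and [icp_fit()].
#' @export
centroid_distance_measure <- function() {
  function(fitted, x, labels) {
    mu <- fitted$model$centroids
    idx <- match(labels, rownames(mu))
    if (anyNA(idx)) stopf("labels outside the fitted label space")
    sqrt(rowSums((x - mu[idx, , drop = FALSE])^2))
  }
}
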