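#' Confidence specification
#'
#' Confidence level and its derived significance level `epsilon = 1 -
#' confidence`. The API speaks in confidence (e.g. 0.95) throughout;
#' prediction regions retain every label whose conformal p-value exceeds
#' `epsilon`.
#'
#' @param confidence real in (0, 1).
#' @return object of class `confidence_spec` with fields `confidence` and
#'   `epsilon`.
#' @export
confidence_spec <- function(confidence) {
  if (!is_scalar_number(confidence) || confidence <= 0 || confidence >= 1) {
    stopf("`confidence` must lie strictly between 0 and 1")
  }
  structure(list(confidence = confidence, epsilon = 1 - confidence),
            class = "confidence_spec")
}

as_confidence <- function(conf) {
  if (inherits(conf, "confidence_spec")) conf else confidence_spec(conf)
}

# ---------------------------------------------------------------------------
# Prediction regions

# Build a prediction_regions object from a p-value matrix (samples x labels).
new_prediction_regions <- function(p_values, conf, sample_ids = NULL) {
  conf <- as_confidence(conf)
  label_space <- colnames(p_values)
  keep <- p_values > conf$epsilon
  region <- apply(keep, 1, function(r) label_space[r], simplify = FALSE)
  sizes <- vapply(region, length, 0L)
  structure(
    list(p_values = p_values,
         region = region,
         size = sizes,
         flag = ifelse(sizes == 1L, "singleton", "uncertain"),
         empty = sizes == 0L,
         confidence = conf,
         label_space = label_space,
         sample_ids = sample_ids %||% rownames(p_values) %||%
           sprintf("T%04d", seq_len(nrow(p_values)))),
    class = "prediction_regions"
  )
}

#' @export
print.prediction_regions <- function(x, ...) {
  cat(sprintf("<prediction_regions> %d samples, labels {%s}, confidence %.2f\n",
              length(x$region), paste(x$label_space, collapse = ", "),
              x$confidence$confidence))
  cat(sprintf("  singleton %d | uncertain %d (of which empty %d)\n",
              sum(x$flag == "singleton"), sum(x$flag == "uncertain"),
              sum(x$empty)))
  invisible(x)
}

#' @export
as.data.frame.prediction_regions <- function(x, ...) {
  df <- data.frame(sample_id = x$sample_ids, stringsAsFactors = FALSE)
  for (lab in x$label_space) df[[paste0("p_", lab)]] <- x$p_values[, lab]
  df$region <- vapply(x$region, paste, "", collapse = ",")
  df$flag <- x$flag
  df
}

#' Write prediction regions as TSV
#'
#' One row per test sample: `sample_id`, one `p_<label>` column per label,
#' `region` (comma-joined retained labels; empty string for the empty set)
#' and `flag` (`singleton`/`uncertain`).
#'
#' @param regions a `prediction_regions` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prediction_regions <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Tabulate prediction-region composition
#'
#' Counts test samples per retained label subset (e.g. `{GCB,ABC}` doubles vs
#' singletons vs the full set) — a compact view of where a conformal
#' classifier hedges.
#'
#' @param regions a `prediction_regions` object.
#' @return data.frame with columns `region`, `size`, `count`.
#' @export
region_composition <- function(regions) {
  key <- vapply(regions$region, function(r) paste(r, collapse = ","), "")
  key[key == ""] <- "(empty)"
  tab <- table(key)
  out <- data.frame(region = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$size <- ifelse(out$region == "(empty)", 0L,
                     lengths(strsplit(out$region, ",", fixed = TRUE)))
  out[order(out$size, out$region), c("region", "size", "count")]
}

# ---------------------------------------------------------------------------
# Transductive conformal prediction

#' Transductive conformal classification
#'
#' The full conformal procedure: for each test sample and each candidate
#' label `y`, the training set is augmented with the test features labelled
#' `y`, the model is retrained, all `n + 1` instances are scored, and the
#' p-value for `y` is the fraction of the `n + 1` scores at least as large
#' as the augmented instance's own score (the augmented instance counts
#' itself, so p-values are at least `1/(n+1)`). Labels with `p > epsilon`
#' form the prediction region. Retraining `K` times per test sample makes
#' this the method of choice for small cohorts where an inductive
#' calibration split would be wasteful.
#'
#' @param dataset classification [labeled_dataset()] (the training data).
#' @param new_features numeric vector (one sample) or matrix of test samples.
#' @param adapter a [model_adapter()].
#' @param measure `"inverse_probability"`, `"hinge"`, or a measure function
#'   `function(fitted, x, labels)`.
#' @param conf confidence level or [confidence_spec()].
#' @param seed seed forwarded to every retraining.
#' @return a `prediction_regions` object (one row per test sample).
#' @export
tcp_predict <- function(dataset, new_features, adapter,
                        measure = "inverse_probability", conf = 0.95,
                        seed = 1L) {
  if (dataset$task != "classification") stopf("tcp_predict requires a classification dataset")
  conf <- as_confidence(conf)
  x <- dataset$features
  labs <- dataset$labels
  space <- dataset$label_space
  if (is.null(dim(new_features))) {
    new_features <- matrix(new_features, nrow = 1)
  }
  new_features <- as.matrix(new_features)
  if (ncol(new_features) != ncol(x)) stopf("test features have %d columns, expected %d",
                                           ncol(new_features), ncol(x))
  n <- nrow(x)
  pmat <- matrix(NA_real_, nrow = nrow(new_features), ncol = length(space),
                 dimnames = list(rownames(new_features), space))
  for (i in seq_len(nrow(new_features))) {
    for (y in space) {
      xa <- rbind(x, new_features[i, , drop = FALSE])
      ya <- c(labs, y)
      fitted <- adapter_fit(adapter, xa, ya, seed = seed, label_space = space)
      alpha <- classification_scores(fitted, xa, ya, measure)
      pmat[i, y] <- sum(alpha >= alpha[n + 1]) / (n + 1)
    }
  }
  new_prediction_regions(pmat, conf)
}

# ---------------------------------------------------------------------------
# Inductive conformal prediction

#' Fit an inductive conformal model
#'
#' Trains the adapter once on the proper training set and scores the
#' disjoint calibration set with the chosen non-conformity measure. The
#' frozen fit plus calibration scores are everything inductive prediction
#' needs.
#'
#' @param train training [labeled_dataset()].
#' @param calibration calibration [labeled_dataset()]; sample ids must be
#'   disjoint from `train` (leakage check) and feature ids identical.
#' @param adapter a [model_adapter()].
#' @param measure non-conformity measure: `"inverse_probability"`/`"hinge"`
#'   (classification), `"absolute_error"` (regression), or a function.
#' @param seed training seed.
#' @return object of class `calibration_model` with the fitted adapter,
#'   calibration `scores`, calibration labels, `n_cal` and `task`.
#' @export
icp_fit <- function(train, calibration, adapter,
                    measure = if (train$task == "classification") "inverse_probability" else "absolute_error",
                    seed = 1L) {
  if (train$task != calibration$task) stopf("train and calibration tasks differ")
  overlap <- intersect(train$sample_ids, calibration$sample_ids)
  if (length(overlap)) {
    stopf("leakage: %d sample(s) appear in both train and calibration (e.g. %s)",
          length(overlap), overlap[1])
  }
  if (!identical(train$feature_ids, calibration$feature_ids)) {
    stopf("train and calibration feature_ids differ")
  }
  task <- train$task
  if (task == "classification") {
    if (!identical(train$label_space, calibration$label_space)) {
      stopf("train and calibration label spaces differ")
    }
    fitted <- adapter_fit(adapter, train$features, train$labels, seed = seed,
                          label_space = train$label_space)
    scores <- classification_scores(fitted, calibration$features,
                                    calibration$labels, measure)
  } else {
    fitted <- adapter_fit(adapter, train$features, train$labels, seed = seed)
    scores <- if (is.function(measure)) {
      as.numeric(measure(fitted, calibration$features, calibration$labels))
    } else {
      measure <- match.arg(measure, "absolute_error")
      absolute_error_score(calibration$labels,
                           predict_point(fitted, calibration$features))
    }
  }
  structure(
    list(fitted = fitted, scores = scores,
         calibration_labels = if (task == "classification") calibration$labels else NULL,
         n_cal = length(scores), task = task, measure = measure,
         label_space = train$label_space, seed = as.integer(seed)),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s | %s | n_cal = %d\n", x$task,
              x$fitted$adapter$name, x$n_cal))
  invisible(x)
}

#' Inductive conformal classification
#'
#' Scores each test sample under every candidate label and converts the
#' scores to conformal p-values against the calibration scores. With
#' `mondrian = TRUE` the comparison is label-conditional (LCMCP): the
#' candidate label's score is ranked only among calibration samples whose
#' true label matches, which restores per-class validity under label shift.
#'
#' @param model a classification [icp_fit()] result.
#' @param test_features feature matrix of test samples.
#' @param conf confidence level or [confidence_spec()].
#' @param mondrian use label-conditional calibration.
#' @return a `prediction_regions` object.
#' @export
icp_classify <- function(model, test_features, conf = 0.95, mondrian = FALSE) {
  if (!inherits(model, "calibration_model") || model$task != "classification") {
    stopf("`model` must be a classification calibration_model")
  }
  conf <- as_confidence(conf)
  test_features <- as.matrix(test_features)
  space <- model$label_space
  if (mondrian) {
    n_by_class <- table(factor(model$calibration_labels, levels = space))
    if (any(n_by_class == 0)) {
      stopf("mondrian calibration requires every class in the calibration set; missing: %s",
            paste(names(n_by_class)[n_by_class == 0], collapse = ", "))
    }
  }
  pmat <- matrix(NA_real_, nrow = nrow(test_features), ncol = length(space),
                 dimnames = list(rownames(test_features), space))
  for (y in space) {
    s <- classification_scores(model$fitted, test_features,
                               rep(y, nrow(test_features)), model$measure)
    ref <- if (mondrian) model$scores[model$calibration_labels == y] else model$scores
    pmat[, y] <- conformal_p_value(ref, s)
  }
  new_prediction_regions(pmat, conf)
}

#' Calibration quantile for inductive conformal regression
#'
#' The conformal half-width at a confidence level: the k-th smallest
#' calibration non-conformity score with `k = ceiling((n_cal + 1) *
#' confidence)`. If `k` exceeds `n_cal` the calibration set is too small for
#' the requested confidence and the interval is unbounded (`Inf`), which
#' preserves the validity guarantee rather than silently clamping.
#'
#' @param model a regression [icp_fit()] result.
#' @param conf confidence level or [confidence_spec()].
#' @return the half-width (possibly `Inf`).
#' @export
icp_regress_quantile <- function(model, conf = 0.95) {
  if (!inherits(model, "calibration_model") || model$task != "regression") {
    stopf("`model` must be a regression calibration_model")
  }
  conf <- as_confidence(conf)
  n <- model$n_cal
  if (n < 1) stopf("empty calibration set")
  k <- ceiling((n + 1) * conf$confidence)
  if (k > n) return(Inf)
  sort(model$scores)[k]
}

#' Inductive conformal regression intervals
#'
#' Symmetric intervals: point prediction plus/minus the calibration quantile
#' of [icp_regress_quantile()]. The half-width is identical across test
#' samples (the absolute-residual measure is not locally adaptive; see the
#' methods vignette).
#'
#' @param model a regression [icp_fit()] result.
#' @param test_features feature matrix.
#' @param conf confidence level or [confidence_spec()].
#' @return data.frame of class `prediction_intervals` with columns
#'   `sample_id`, `center`, `half_width`, `lower`, `upper`, `unbounded`.
#' @export
icp_regress_predict <- function(model, test_features, conf = 0.95) {
  conf <- as_confidence(conf)
  test_features <- as.matrix(test_features)
  hw <- icp_regress_quantile(model, conf)
  center <- predict_point(model$fitted, test_features)
  out <- data.frame(
    sample_id = rownames(test_features) %||% sprintf("T%04d", seq_along(center)),
    center = center,
    half_width = hw,
    lower = center - hw,
    upper = center + hw,
    unbounded = is.infinite(hw),
    stringsAsFactors = FALSE
  )
  attr(out, "confidence") <- conf
  class(out) <- c("prediction_intervals", "data.frame")
  out
}

#' Write prediction intervals as TSV
#'
#' @param intervals a `prediction_intervals` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prediction_intervals <- function(intervals, path) {
  utils::write.table(intervals[, c("sample_id", "center", "lower", "upper", "unbounded")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
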