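# Evaluation of conformal predictors: coverage, uncertainty, adaptivity.

region_list <- function(regions) {
  if (inherits(regions, "prediction_regions")) regions$region else regions
}

#' Empirical coverage
#'
#' Fraction of evaluation samples whose true label falls inside the
#' prediction region (classification) or whose true value falls inside the
#' prediction interval (regression).
#'
#' @param regions a `prediction_regions` object, a list of label vectors, or
#'   a `prediction_intervals` data.frame.
#' @param truths true labels (character) or true responses (numeric).
#' @return coverage in `[0, 1]`.
#' @export
empirical_coverage <- function(regions, truths) {
  if (inherits(regions, "prediction_intervals") ||
      (is.data.frame(regions) && all(c("lower", "upper") %in% names(regions)))) {
    if (nrow(regions) != length(truths)) stopf("regions and truths differ in length")
    return(mean(truths >= regions$lower & truths <= regions$upper))
  }
  rl <- region_list(regions)
  if (length(rl) != length(truths)) stopf("regions and truths differ in length")
  truths <- as.character(truths)
  mean(vapply(seq_along(rl), function(i) truths[i] %in% rl[[i]], NA))
}

#' Uncertain-prediction (UNC) rate
#'
#' Fraction of regions that are not singletons; the empty region counts as
#' uncertain (it signals that no label conforms at the chosen confidence).
#'
#' @param regions a `prediction_regions` object or list of label vectors.
#' @return rate in `[0, 1]`.
#' @export
unc_rate <- function(regions) {
  rl <- region_list(regions)
  if (length(rl) == 0) stopf("no regions supplied")
  mean(lengths(rl) != 1L)
}

#' @rdname unc_rate
#' @export
singleton_rate <- function(regions) 1 - unc_rate(regions)

#' Error-detection rate
#'
#' Among samples the base (non-conformalized) model misclassifies, the
#' fraction the conformal layer flags as uncertain (non-singleton region).
#' Undefined — `NA`, not 0 — when the base model makes no errors, so a
#' perfect base model never masquerades as perfect error detection.
#'
#' @param base_predictions the base model's point predictions.
#' @param regions a `prediction_regions` object or list of label vectors.
#' @param truths true labels.
#' @return rate in `[0, 1]`, or `NA_real_` when there are no base errors.
#' @export
error_detection <- function(base_predictions, regions, truths) {
  rl <- region_list(regions)
  if (length(rl) != length(truths) || length(base_predictions) != length(truths)) {
    stopf("base_predictions, regions and truths must have equal length")
  }
  err <- as.character(base_predictions) != as.character(truths)
  if (!any(err)) return(NA_real_)
  mean(lengths(rl)[err] != 1L)
}

#' Size-stratified coverage (SSC)
#'
#' Coverage computed separately within each prediction-set size, the
#' adaptivity diagnostic: an adaptive predictor keeps coverage near the
#' nominal level within every stratum rather than overcovering easy
#' singletons and undercovering hard multiples. Strata with zero count are
#' omitted; counts sum to the number of test samples.
#'
#' @param regions a `prediction_regions` object or list of label vectors.
#' @param truths true labels.
#' @return data.frame with columns `size`, `count`, `coverage`.
#' @export
size_stratified_coverage <- function(regions, truths) {
  rl <- region_list(regions)
  if (length(rl) != length(truths)) stopf("regions and truths differ in length")
  truths <- as.character(truths)
  sizes <- lengths(rl)
  hit <- vapply(seq_along(rl), function(i) truths[i] %in% rl[[i]], NA)
  out <- do.call(rbind, lapply(sort(unique(sizes)), function(s) {
    idx <- sizes == s
    data.frame(size = s, count = sum(idx), coverage = mean(hit[idx]))
  }))
  rownames(out) <- NULL
  out
}

#' Coverage report
#'
#' Bundles the conformal performance metrics for one evaluation cohort:
#' empirical coverage, error rate (`1 - coverage`), UNC and singleton rates,
#' error detection against an optional base model, and size-stratified
#' coverage.
#'
#' @param regions a `prediction_regions` object.
#' @param truths true labels.
#' @param base_predictions optional base-model point predictions.
#' @return object of class `coverage_report`.
#' @export
coverage_report <- function(regions, truths, base_predictions = NULL) {
  cov <- empirical_coverage(regions, truths)
  unc <- unc_rate(regions)
  ed <- if (is.null(base_predictions)) NA_real_ else {
    error_detection(base_predictions, regions, truths)
  }
  structure(
    list(n_test = length(truths),
         empirical_coverage = cov,
         error_rate = 1 - cov,
         unc_rate = unc,
         singleton_rate = 1 - unc,
         error_detection = ed,
         base_error_rate = if (is.null(base_predictions)) NA_real_ else {
           mean(as.character(base_predictions) != as.character(truths))
         },
         ssc = size_stratified_coverage(regions, truths)),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("<coverage_report> n_test = %d\n", x$n_test))
  cat(sprintf("  empirical coverage %s | error rate %s\n",
              pct(x$empirical_coverage), pct(x$error_rate)))
  cat(sprintf("  UNC rate %s | singleton rate %s\n",
              pct(x$unc_rate), pct(x$singleton_rate)))
  cat(sprintf("  base error rate %s | error detection %s\n",
              pct(x$base_error_rate), pct(x$error_detection)))
  cat("  size-stratified coverage:\n")
  for (i in seq_len(nrow(x$ssc))) {
    cat(sprintf("    size %d: n = %d, coverage %s\n", x$ssc$size[i],
                x$ssc$count[i], pct(x$ssc$coverage[i])))
  }
  invisible(x)
}

#' Serialize a coverage report as JSON
#'
#' Rates are stored as fractions (the print method formats percents).
#'
#' @param report a [coverage_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Coverage distribution over repeated calibration/test splits
#'
#' Repeats the inductive pipeline on fresh seeded train/calibration/test
#' splits of one dataset and records the empirical coverage of each repeat —
#' the recommended check that nominal coverage holds not just on one lucky
#' split. Under exchangeability the repeat coverages concentrate around the
#' confidence level following the calibration-size Beta law.
#'
#' @param dataset classification [labeled_dataset()].
#' @param adapter a [model_adapter()].
#' @param measure non-conformity measure (see [icp_fit()]).
#' @param conf confidence level or [confidence_spec()].
#' @param n_repeats number of repeats.
#' @param seed master seed; per-repeat seeds are derived from it.
#' @param fractions train/calibration/test fractions.
#' @param stratified stratify splits by class.
#' @param mondrian label-conditional calibration.
#' @return numeric vector of per-repeat coverages.
#' @export
repeated_split_coverage <- function(dataset, adapter,
                                    measure = "inverse_probability",
                                    conf = 0.9, n_repeats = 100, seed = 1L,
                                    fractions = c(0.6, 0.2, 0.2),
                                    stratified = TRUE, mondrian = FALSE) {
  if (n_repeats < 1) stopf("`n_repeats` must be at least 1")
  conf <- as_confidence(conf)
  seeds <- derive_seeds(seed, n_repeats)
  vapply(seq_len(n_repeats), function(i) {
    plan <- make_split(dataset, fractions, stratified = stratified,
                       seed = seeds[i])
    parts <- split_dataset(dataset, plan)
    model <- icp_fit(parts$train, parts$calibration, adapter,
                     measure = measure, seed = seeds[i])
    regions <- icp_classify(model, parts$test$features, conf,
                            mondrian = mondrian)
    empirical_coverage(regions, parts$test$labels)
  }, 0)
}
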