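#' Labeled expression dataset
#'
#' The package's core data container: a samples-by-features numeric matrix
#' together with per-sample labels. Labels are either categorical (molecular
#' subtype, responder status) or continuous (an IC50-like drug response);
#' the task is inferred from the label type.
#'
#' @param features numeric matrix, samples in rows, features in columns.
#' @param labels character/factor vector (classification) or numeric vector
#'   (regression), one per row of `features`.
#' @param sample_ids unique sample identifiers; defaults to the row names of
#'   `features` or `S0001`-style ids.
#' @param feature_ids unique feature identifiers; defaults to column names or
#'   `gene_0001`-style ids.
#' @param label_space ordered vector of category names (classification only).
#'   Defaults to the sorted unique labels; per package convention all
#'   per-label vectors follow lexicographic label order.
#' @param metadata free-form list (e.g. generator provenance).
#'
#' @return an object of class `labeled_dataset` with elements `features`,
#'   `labels`, `sample_ids`, `feature_ids`, `label_space`, `task`, `metadata`.
#' @export
labeled_dataset <- function(features, labels, sample_ids = NULL,
                            feature_ids = NULL, label_space = NULL,
                            metadata = list()) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stopf("`features` must be a numeric matrix")
  n <- nrow(features)
  p <- ncol(features)
  if (length(labels) != n) {
    stopf("length of `labels` (%d) must equal the number of samples (%d)",
          length(labels), n)
  }
  if (anyNA(features)) stopf("`features` contains missing values")
  if (anyNA(labels)) stopf("`labels` contains missing values")

  sample_ids <- sample_ids %||% rownames(features) %||% sprintf("S%04d", seq_len(n))
  feature_ids <- feature_ids %||% colnames(features) %||% sprintf("gene_%04d", seq_len(p))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != n) stopf("`sample_ids` must have one entry per sample")
  if (length(feature_ids) != p) stopf("`feature_ids` must have one entry per feature")
  if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample_ids: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_ids)) stopf("duplicate feature_ids")

  if (is.numeric(labels)) {
    task <- "regression"
    labels <- as.numeric(labels)
    if (any(!is.finite(labels))) stopf("regression labels must be finite")
    label_space <- NULL
  } else {
    task <- "classification"
    labels <- as.character(labels)
    label_space <- label_space %||% sort(unique(labels))
    label_space <- as.character(label_space)
    if (!all(labels %in% label_space)) {
      stopf("labels outside label_space: %s",
            paste(setdiff(unique(labels), label_space), collapse = ", "))
    }
  }
  dimnames(features) <- list(sample_ids, feature_ids)

  structure(
    list(features = features, labels = labels, sample_ids = sample_ids,
         feature_ids = feature_ids, label_space = label_space, task = task,
         metadata = metadata),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features (%s)\n",
              length(x$sample_ids), length(x$feature_ids), x$task))
  if (x$task == "classification") {
    tab <- table(factor(x$labels, levels = x$label_space))
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  } else {
    cat(sprintf("  response range: [%.4g, %.4g]\n",
                min(x$labels), max(x$labels)))
  }
  invisible(x)
}

#' Number of samples in a dataset
#' @param dataset a [labeled_dataset()].
#' @return integer sample count.
#' @export
n_samples <- function(dataset) length(dataset$sample_ids)

#' Subset a dataset by samples and/or features
#'
#' @param dataset a [labeled_dataset()].
#' @param samples sample ids or indices (default: all).
#' @param features feature ids or indices (default: all).
#' @return a `labeled_dataset` restricted to the requested rows/columns.
#'   The label space is preserved even if a class drops out of the subset.
#' @export
subset_dataset <- function(dataset, samples = NULL, features = NULL) {
  i <- samples %||% seq_along(dataset$sample_ids)
  j <- features %||% seq_along(dataset$feature_ids)
  if (is.character(i)) {
    miss <- setdiff(i, dataset$sample_ids)
    if (length(miss)) stopf("unknown sample_ids: %s", paste(miss, collapse = ", "))
    i <- match(i, dataset$sample_ids)
  }
  if (is.character(j)) {
    miss <- setdiff(j, dataset$feature_ids)
    if (length(miss)) stopf("unknown feature_ids: %s", paste(miss, collapse = ", "))
    j <- match(j, dataset$feature_ids)
  }
  labeled_dataset(dataset$features[i, j, drop = FALSE], dataset$labels[i],
                  sample_ids = dataset$sample_ids[i],
                  feature_ids = dataset$feature_ids[j],
                  label_space = dataset$label_space,
                  metadata = dataset$metadata)
}

#' Read a labeled expression table
#'
#' Expects the package's TSV layout: samples in rows, first column
#' `sample_id`, last column `label` (classification) or `response`
#' (regression), remaining columns numeric feature values. A gene-major
#' matrix (features in rows, as in GEO series matrices) can be read with
#' `genes_in_rows = TRUE` plus an explicit `labels` vector.
#'
#' @param path TSV file path.
#' @param genes_in_rows if `TRUE`, the file holds features in rows (first
#'   column = feature id, remaining columns = samples) and carries no label
#'   column; `labels` must then be supplied.
#' @param labels optional labels used with `genes_in_rows = TRUE`.
#' @param label_space optional explicit label space.
#' @return a [labeled_dataset()].
#' @export
read_expression_table <- function(path, genes_in_rows = FALSE, labels = NULL,
                                  label_space = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2) stopf("parse error in %s: need a header plus data rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stopf("parse error in %s at line %d: %d fields, expected %d",
          path, bad, widths[bad], widths[1])
  }
  header <- fields[[1]]
  body <- fields[-1]

  if (genes_in_rows) {
    feature_ids <- vapply(body, `[`, "", 1L)
    mat <- t(vapply(body, function(f) suppressWarnings(as.numeric(f[-1])),
                    numeric(length(header) - 1L)))
    if (anyNA(mat)) {
      bad <- which(apply(mat, 1, anyNA))[1] + 1L
      stopf("parse error in %s at line %d: missing or non-numeric cell", path, bad)
    }
    mat <- t(mat)
    rownames(mat) <- header[-1]
    colnames(mat) <- feature_ids
    if (is.null(labels)) {
      stopf("unlabeled matrix: %s has no label column; supply `labels`", path)
    }
    return(labeled_dataset(mat, labels, sample_ids = header[-1],
                           feature_ids = feature_ids, label_space = label_space))
  }

  if (header[1] != "sample_id") {
    stopf("parse error in %s: first column must be `sample_id`, found `%s`",
          path, header[1])
  }
  last <- header[length(header)]
  if (!last %in% c("label", "response")) {
    stopf("unlabeled matrix: %s has no terminal `label` or `response` column", path)
  }
  p <- length(header) - 2L
  if (p < 1) stopf("parse error in %s: no feature columns", path)
  sample_ids <- vapply(body, `[`, "", 1L)
  lab_raw <- vapply(body, `[`, "", length(header))
  feat <- t(vapply(body, function(f) {
    suppressWarnings(as.numeric(f[seq(2L, length(header) - 1L)]))
  }, numeric(p)))
  if (p == 1L) feat <- matrix(feat, ncol = 1L)
  if (anyNA(feat)) {
    bad <- which(apply(feat, 1, anyNA))[1] + 1L
    stopf("parse error in %s at line %d: missing or non-numeric feature cell",
          path, bad)
  }
  if (last == "response") {
    lab <- suppressWarnings(as.numeric(lab_raw))
    if (anyNA(lab)) {
      bad <- which(is.na(lab))[1] + 1L
      stopf("parse error in %s at line %d: non-numeric response", path, bad)
    }
  } else {
    if (any(!nzchar(lab_raw))) {
      bad <- which(!nzchar(lab_raw))[1] + 1L
      stopf("parse error in %s at line %d: empty label", path, bad)
    }
    lab <- lab_raw
  }
  labeled_dataset(feat, lab, sample_ids = sample_ids,
                  feature_ids = header[seq(2L, length(header) - 1L)],
                  label_space = label_space)
}

#' Write a labeled expression table
#'
#' Inverse of [read_expression_table()]: numeric cells are written with 17
#' significant digits so a write/read round trip reproduces the dataset
#' exactly.
#'
#' @param dataset a [labeled_dataset()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(dataset, path) {
  lab_col <- if (dataset$task == "classification") "label" else "response"
  lab <- if (dataset$task == "classification") {
    dataset$labels
  } else {
    sprintf("%.17g", dataset$labels)
  }
  header <- paste(c("sample_id", dataset$feature_ids, lab_col), collapse = "\t")
  rows <- vapply(seq_along(dataset$sample_ids), function(i) {
    paste(c(dataset$sample_ids[i],
            sprintf("%.17g", dataset$features[i, ]),
            lab[i]), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}
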