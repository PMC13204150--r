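#' Labeled feature-table datasets
#'
#' The pipeline's common currency: a numeric samples-by-features matrix with
#' binary class labels (0 = healthy, 1 = AD), unique feature names and sample
#' identifiers. Constructed directly, by [load_dataset()], or by
#' [generate_dataset()].
#'
#' @param features numeric matrix (or data frame of numeric columns),
#'   samples in rows.
#' @param labels vector of 0/1 class labels, one per row.
#' @param feature_names optional character vector of unique feature names.
#' @param sample_ids optional character vector of sample identifiers.
#' @return An object of class `labeled_dataset` with elements `features`
#'   (matrix), `labels` (integer), `feature_names`, `sample_ids`.
#' @export
labeled_dataset <- function(features, labels, feature_names = NULL, sample_ids = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("`features` must be numeric", call. = FALSE)
  n <- nrow(features)
  p <- ncol(features)
  if (length(labels) != n) {
    stop(sprintf("label vector length (%d) must equal sample count (%d)",
                 length(labels), n), call. = FALSE)
  }
  lab <- as.integer(labels)
  if (anyNA(lab) || !all(lab %in% c(0L, 1L))) {
    bad <- which(is.na(lab) | !(lab %in% c(0L, 1L)))[1L]
    stop(sprintf("labels must be binary 0/1; offending row %d has value '%s'",
                 bad, as.character(labels[bad])), call. = FALSE)
  }
  if (any(!is.finite(features))) {
    idx <- which(!is.finite(features), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite feature value at row %d, column %d",
                 idx[1L], idx[2L]), call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) feature_names <- sprintf("f%03d", seq_len(p))
  }
  if (anyDuplicated(feature_names)) stop("feature names must be unique", call. = FALSE)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(features)
    if (is.null(sample_ids)) sample_ids <- sprintf("s%05d", seq_len(n))
  }
  colnames(features) <- feature_names
  rownames(features) <- sample_ids
  structure(list(features = features, labels = lab,
                 feature_names = as.character(feature_names),
                 sample_ids = as.character(sample_ids)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d samples x %d features; class 0: %d, class 1: %d>\n",
              nrow(x$features), ncol(x$features),
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$features)

#' @export
summary.labeled_dataset <- function(object, ...) {
  cat(sprintf("labeled_dataset: n = %d, p = %d\n", nrow(object$features),
              ncol(object$features)))
  cat(sprintf("  class counts: healthy (0) = %d, AD (1) = %d (%.1f%% minority)\n",
              sum(object$labels == 0L), sum(object$labels == 1L),
              100 * mean(object$labels == 1L)))
  invisible(object)
}

subset_dataset <- function(ds, rows = NULL, cols = NULL) {
  f <- ds$features
  l <- ds$labels
  if (!is.null(rows)) { f <- f[rows, , drop = FALSE]; l <- l[rows] }
  if (!is.null(cols)) f <- f[, cols, drop = FALSE]
  labeled_dataset(f, l, colnames(f), rownames(f))
}

#' Read a labeled dataset from CSV
#'
#' Expects comma-separated text with a header row; all non-label columns must
#' be numeric, the label column binary 0/1. Cells that fail to parse (or are
#' NaN/Inf) are rejected with their coordinates.
#'
#' @param path path to a CSV file.
#' @param label_column name of the label column (default `"label"`).
#' @return A [labeled_dataset()]; row order is preserved.
#' @export
load_dataset <- function(path, label_column = "label") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!label_column %in% names(df)) {
    stop(sprintf("label column '%s' not found in %s", label_column, path), call. = FALSE)
  }
  labels <- df[[label_column]]
  feat <- df[, setdiff(names(df), label_column), drop = FALSE]
  for (j in seq_along(feat)) {
    col <- feat[[j]]
    if (is.character(col) || is.logical(col) || is.factor(col)) {
      num <- suppressWarnings(as.numeric(as.character(col)))
      bad <- which(is.na(num))
      if (length(bad)) {
        stop(sprintf("non-numeric feature cell at row %d, column '%s'",
                     bad[1L], names(feat)[j]), call. = FALSE)
      }
      feat[[j]] <- num
    }
    notfin <- which(!is.finite(feat[[j]]))
    if (length(notfin)) {
      stop(sprintf("non-finite value (NaN/Inf/NA) at row %d, column '%s'",
                   notfin[1L], names(feat)[j]), call. = FALSE)
    }
  }
  labeled_dataset(as.matrix(feat), labels)
}

#' Write a labeled dataset to CSV
#'
#' Values are written with 17 significant digits so that decimal-representable
#' doubles round-trip exactly through [load_dataset()].
#'
#' @param dataset a [labeled_dataset()].
#' @param path output path.
#' @param label_column name to give the label column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, label_column = "label") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- as.data.frame(dataset$features)
  df[[label_column]] <- dataset$labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(colnames(dataset$features), label_column), collapse = ","), con)
  body <- apply(dataset$features, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(paste(body, dataset$labels, sep = ","), con)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' A run configuration names one component per stage plus the CV plan:
#' `extractor`/`selector`/`classifier` objects with `name` and optional
#' `params`, and `cv` with `folds`, `repeats`; plus a master `seed`.
#'
#' @param path path to a JSON file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(extractor = cfg$extractor, selector = cfg$selector,
             classifier = cfg$classifier,
             folds = cfg$cv$folds %||% 10L, repeats = cfg$cv$repeats %||% 5L,
             seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_component <- function(x, default_name) {
  if (is.null(x)) return(list(name = default_name, params = list()))
  if (is.character(x)) return(list(name = x, params = list()))
  list(name = x$name %||% default_name, params = as.list(x$params %||% list()))
}

#' Assemble and validate a run configuration
#'
#' @param extractor,selector,classifier component name (character) or list
#'   with `name` and `params`.
#' @param folds,repeats CV geometry; `folds >= 2`, `repeats >= 1`.
#' @param seed non-negative integer master seed.
#' @export
run_config <- function(extractor = "none", selector = "none",
                       classifier = "elm_adaboost",
                       folds = 10L, repeats = 5L, seed = 1L) {
  cfg <- list(extractor = as_component(extractor, "none"),
              selector = as_component(selector, "none"),
              classifier = as_component(classifier, "elm_adaboost"),
              folds = as.integer(folds), repeats = as.integer(repeats),
              seed = seed)
  if (!cfg$extractor$name %in% extractor_names())
    stop(sprintf("unknown extractor '%s'", cfg$extractor$name), call. = FALSE)
  if (!cfg$selector$name %in% selector_names())
    stop(sprintf("unknown selector '%s'", cfg$selector$name), call. = FALSE)
  if (!cfg$classifier$name %in% classifier_names())
    stop(sprintf("unknown classifier '%s'", cfg$classifier$name), call. = FALSE)
  if (cfg$folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (cfg$repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  if (!is.numeric(seed) || seed < 0 || seed != floor(seed))
    stop("seed must be a non-negative integer", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config: %s -> %s -> %s | %d-fold x %d repeats, seed %s>\n",
              x$extractor$name, x$selector$name, x$classifier$name,
              x$folds, x$repeats, format(x$seed)))
  invisible(x)
}
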