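#' Cross-validation plan
#'
#' Repeated stratified k-fold: every sample appears in exactly one test fold
#' per repeat, and per-fold class counts stay within one sample of the
#' global class ratio.
#'
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats repeats (default 5).
#' @param stratified stratify folds by class (default TRUE).
#' @param seed master seed for the fold shuffles.
#' @export
cv_plan <- function(n_folds = 10L, n_repeats = 5L, stratified = TRUE,
                    seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified), seed = seed),
            class = "cv_plan")
}

plan_folds <- function(labels, plan, repeat_i) {
  s <- rng_stream(plan$seed, sprintf("folds/r%d", repeat_i))
  if (plan$stratified) {
    make_stratified_folds(labels, plan$n_folds, s)
  } else {
    idx <- stream_sample(s, length(labels))
    fold <- integer(length(labels))
    fold[idx] <- ((seq_along(idx) - 1L) %% plan$n_folds) + 1L
    fold
  }
}

#' Leakage-free cross-validation of one pipeline configuration
#'
#' For every repeat and fold: the extractor is fitted on the training rows
#' only and applied to both portions; the selector optimizes its wrapper
#' fitness with inner folds of the training portion only; the classifier is
#' trained on the selected training features; test accuracy is
#' `(N - E)/N * 100`. No test-fold information reaches any fitting stage.
#'
#' @param dataset a [labeled_dataset()].
#' @param config a [run_config()] (or arguments accepted by it, as a list).
#' @param plan a [cv_plan()]; defaults to `config$folds` x `config$repeats`
#'   seeded by `config$seed`.
#' @param select_once if `TRUE`, the selector (and its extractor) run once
#'   on the full dataset before CV and the mask is reused across folds —
#'   the optimistic, leaky protocol variant, exposed so the gap against the
#'   per-fold default can be quantified.
#' @return Object of class `cv_result` with per-fold accuracies and
#'   confusion counts.
#' @export
cross_validate <- function(dataset, config, plan = NULL, select_once = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  if (is.null(plan)) {
    plan <- cv_plan(config$folds, config$repeats, seed = config$seed)
  }
  y <- dataset$labels
  X <- dataset$features
  global_mask <- NULL
  if (select_once && config$selector$name != "none") {
    ex0 <- fit_extractor(config$extractor$name, X, y, config$extractor$params,
                         rng_stream(config$seed, "extract/global"))
    Z0 <- predict(ex0, X)
    global_mask <- select_features(Z0, y, config$selector$name,
                                   config$selector$params,
                                   stream = rng_stream(config$seed,
                                                       "select/global"))$mask
  }
  rows <- list()
  for (r in seq_len(plan$n_repeats)) {
    fold <- plan_folds(y, plan, r)
    for (f in seq_len(plan$n_folds)) {
      tag <- sprintf("r%df%d", r, f)
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) {
        fold <- plan_folds(y, plan, r + 1000L)   # re-stratification retry
        tr <- fold != f
        if (length(unique(y[tr])) < 2L)
          stop("training fold with a single class", call. = FALSE)
      }
      ex <- fit_extractor(config$extractor$name, X[tr, , drop = FALSE], y[tr],
                          config$extractor$params,
                          rng_stream(config$seed, paste0("extract/", tag)))
      Ztr <- predict(ex, X[tr, , drop = FALSE])
      Zte <- predict(ex, X[!tr, , drop = FALSE])
      mask <- if (!is.null(global_mask)) {
        global_mask
      } else if (config$selector$name == "none") {
        rep(1L, ncol(Ztr))
      } else {
        select_features(Ztr, y[tr], config$selector$name,
                        config$selector$params,
                        stream = rng_stream(config$seed,
                                            paste0("select/", tag)))$mask
      }
      sel <- which(mask == 1L)
      clf <- fit_classifier(config$classifier$name,
                            Ztr[, sel, drop = FALSE], y[tr],
                            config$classifier$params,
                            rng_stream(config$seed, paste0("clf/", tag)))
      pred <- predict(clf, Zte[, sel, drop = FALSE])
      truth <- y[!tr]
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_i = r, fold = f,
        accuracy = 100 * mean(pred == truth),
        tp = sum(pred == 1L & truth == 1L), tn = sum(pred == 0L & truth == 0L),
        fp = sum(pred == 1L & truth == 0L), fn = sum(pred == 0L & truth == 1L),
        n_selected = length(sel))
    }
  }
  folds_df <- do.call(rbind, rows)
  structure(list(folds = folds_df, mean_accuracy = mean(folds_df$accuracy),
                 sd_accuracy = stats::sd(folds_df$accuracy),
                 config = config, plan = plan, select_once = select_once),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s|%s|%s: %.2f%% (sd %.2f) over %d folds>\n",
              x$config$extractor$name, x$config$selector$name,
              x$config$classifier$name, x$mean_accuracy, x$sd_accuracy,
              nrow(x$folds)))
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  print(object)
  cm <- colSums(object$folds[, c("tp", "tn", "fp", "fn")])
  sens <- cm["tp"] / (cm["tp"] + cm["fn"])
  spec <- cm["tn"] / (cm["tn"] + cm["fp"])
  cat(sprintf("  pooled sensitivity %.3f, specificity %.3f, mean |mask| %.1f\n",
              sens, spec, mean(object$folds$n_selected)))
  invisible(object)
}

as_component_list <- function(x) {
  if (is.character(x)) return(lapply(x, function(nm) list(name = nm, params = list())))
  lapply(x, function(e) as_component(e, "none"))
}

#' Run the extractor x selector x classifier experiment grid
#'
#' Cross-validates every combination of the given component lists; each cell
#' gets its own seed derived from the cell coordinates so results are
#' independent of execution order.
#'
#' @param dataset a [labeled_dataset()].
#' @param extractors,selectors,classifiers character vectors of component
#'   names, or lists of `list(name=, params=)`.
#' @param plan a [cv_plan()].
#' @param seed master seed.
#' @param experiment label stored with every row (e.g. `"experiment1"`).
#' @param verbose print one line per finished cell.
#' @return Object of class `results_table`: a data frame with one row per
#'   grid cell (mean accuracy, dispersion) and per-fold values attached.
#' @export
run_grid <- function(dataset, extractors, selectors, classifiers,
                     plan = cv_plan(), seed = 1L, experiment = "experiment1",
                     verbose = FALSE) {
  exs <- as_component_list(extractors)
  ses <- as_component_list(selectors)
  cls <- as_component_list(classifiers)
  if (!length(exs) || !length(ses) || !length(cls))
    stop("component lists must be non-empty", call. = FALSE)
  rows <- list(); fold_values <- list()
  for (se in ses) for (ex in exs) for (cl in cls) {
    tag <- paste(ex$name, se$name, cl$name, sep = "|")
    cell_seed <- derive_seed(seed, paste0("grid/", tag))
    cfg <- run_config(extractor = ex, selector = se, classifier = cl,
                      folds = plan$n_folds, repeats = plan$n_repeats,
                      seed = cell_seed)
    cv <- cross_validate(dataset, cfg,
                         cv_plan(plan$n_folds, plan$n_repeats, seed = cell_seed))
    rows[[tag]] <- data.frame(
      experiment = experiment, extractor = ex$name, selector = se$name,
      classifier = cl$name, mean_accuracy = cv$mean_accuracy,
      sd_accuracy = cv$sd_accuracy, n_folds = nrow(cv$folds))
    fold_values[[tag]] <- cv$folds$accuracy
    if (verbose) {
      message(sprintf("[grid] %-40s %.2f%% (sd %.2f)", tag,
                      cv$mean_accuracy, cv$sd_accuracy))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fold_values") <- fold_values
  attr(out, "seed") <- seed
  class(out) <- c("results_table", "data.frame")
  out
}

#' @export
print.results_table <- function(x, ...) {
  cat(sprintf("<results_table: %d cells>\n", nrow(x)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Summarize the best grid cells
#'
#' Ranks cells by mean accuracy; ties are broken lexicographically by
#' (selector, extractor, classifier).
#'
#' @param results a `results_table` from [run_grid()].
#' @param best_k number of top combinations to return.
#' @return Data frame of the top `best_k` rows, ranked.
#' @export
report <- function(results, best_k = 5L) {
  if (!nrow(results)) stop("empty results table", call. = FALSE)
  ord <- order(-results$mean_accuracy, results$selector, results$extractor,
               results$classifier)
  top <- utils::head(results[ord, , drop = FALSE], best_k)
  top$rank <- seq_len(nrow(top))
  rownames(top) <- NULL
  class(top) <- "data.frame"
  top
}

#' Write a results table to CSV
#'
#' @param results a `results_table`.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
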