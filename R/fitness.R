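#' Stratified fold assignment
#'
#' Deals each class's (shuffled) samples round-robin over folds, so per-fold
#' class counts are within one sample of proportional allocation.
#'
#' @param labels 0/1 label vector.
#' @param nfold number of folds (>= 2).
#' @param stream an [rng_stream()] used for the within-class shuffle.
#' @return integer vector of fold ids in `1:nfold`.
#' @export
make_stratified_folds <- function(labels, nfold, stream) {
  n <- length(labels)
  fold <- integer(n)
  offset <- 0L
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[stream_sample(stream, length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% nfold) + 1L
    offset <- offset + length(idx)          # stagger classes across folds
  }
  fold
}

#' Binarize a continuous optimizer position
#'
#' Sigmoid transfer `s(x) = 1/(1+exp(-x))` thresholded at 0.5, i.e. a bit is
#' set iff its coordinate is positive. An all-zero mask is repaired by
#' activating `repair_feature` (the feature most correlated with the labels).
#'
#' @param position numeric vector or matrix (rows = candidates).
#' @param repair_feature column index used to repair empty masks.
#' @return integer 0/1 vector or matrix of the same shape, each row with at
#'   least one bit set. Number of repairs applied is attached as
#'   `attr(, "repairs")`.
#' @export
binarize <- function(position, repair_feature = 1L) {
  vec <- is.null(dim(position))
  M <- if (vec) matrix(position, 1L) else as.matrix(position)
  B <- (M > 0) * 1L
  empty <- rowSums(B) == 0L
  if (any(empty)) B[empty, repair_feature] <- 1L
  out <- if (vec) B[1L, ] else B
  attr(out, "repairs") <- sum(empty)
  out
}

#' Mantegna-generated Levy-flight steps
#'
#' Heavy-tailed steps with tail exponent `lambda`, scaled by `alpha`; the
#' proposal mechanism of cuckoo search.
#'
#' @param stream an [rng_stream()].
#' @param lambda tail exponent in (1, 3]; the Mantegna stability index is
#'   capped at 2.
#' @param alpha step scale (>= 0).
#' @param dim number of step components.
#' @export
levy_step <- function(stream, lambda = 1.5, alpha = 0.5, dim = 1L) {
  if (lambda <= 1 || lambda > 3)
    stop("lambda must lie in (1, 3]", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  beta <- min(lambda, 2)
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stream_rnorm(stream, dim, sd = sigma_u)
  v <- stream_rnorm(stream, dim)
  alpha * u / abs(v)^(1 / beta)
}

# Shared wrapper-fitness evaluator: stratified inner kNN CV with a
# mask-keyed cache. The inner folds (and any row subsample) are fixed once
# per evaluator, so fitness is a deterministic function of the mask.
new_fitness_env <- function(X, y, stream, inner_folds = 3L, knn_k = 5L,
                            max_n = 300L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) > max_n) {
    keep0 <- which(y == 0L); keep1 <- which(y == 1L)
    n0 <- max(2L, round(max_n * length(keep0) / length(y)))
    n1 <- max(2L, max_n - n0)
    rows <- c(keep0[stream_sample(stream, length(keep0))][seq_len(min(n0, length(keep0)))],
              keep1[stream_sample(stream, length(keep1))][seq_len(min(n1, length(keep1)))])
    X <- X[rows, , drop = FALSE]; y <- y[rows]
  }
  env <- new.env(parent = emptyenv())
  env$X <- X
  env$y <- y
  env$fold <- make_stratified_folds(y, inner_folds, stream)
  env$nfold <- as.integer(inner_folds)
  env$k <- as.integer(knn_k)
  env$cache <- new.env(parent = emptyenv())
  env$evals <- 0L
  env$repairs <- 0L
  # point-biserial repair feature: highest |correlation| with the labels
  cors <- suppressWarnings(abs(stats::cor(X, y)))
  cors[is.na(cors)] <- 0
  env$repair_feature <- which.max(cors)
  env
}

mask_keys <- function(M) {
  apply(M, 1L, function(r) rawToChar(as.raw(r + 48L)))
}

# Evaluate a matrix of masks (rows); cached per distinct mask.
evaluate_masks <- function(fenv, M) {
  keys <- mask_keys(M)
  out <- numeric(nrow(M))
  hit <- vapply(keys, function(k) !is.null(fenv$cache[[k]]), logical(1L))
  if (any(hit)) out[hit] <- vapply(keys[hit], function(k) fenv$cache[[k]], numeric(1L))
  todo <- which(!hit)
  if (length(todo)) {
    # each distinct new mask is evaluated once
    first <- todo[!duplicated(keys[todo])]
    vals <- knn_cv_fitness_batch_cpp(fenv$X, M[first, , drop = FALSE],
                                     fenv$fold, fenv$y, fenv$k, fenv$nfold)
    fenv$evals <- fenv$evals + length(first)
    for (i in seq_along(first)) fenv$cache[[keys[first[i]]]] <- vals[i]
    out[todo] <- vapply(keys[todo], function(k) fenv$cache[[k]], numeric(1L))
  }
  out
}

#' Wrapper fitness of a feature mask
#'
#' Mean stratified inner-fold CV accuracy (in percent) of a base classifier
#' trained on the masked features: `(1/S) * sum_s (N_s - E_s)/N_s * 100`.
#' The default base classifier is 5-nearest-neighbours; any registered
#' classifier name may be substituted at higher cost.
#'
#' @param mask 0/1 inclusion vector (at least one feature; an empty mask is
#'   repaired to the single most label-correlated feature).
#' @param dataset a [labeled_dataset()], or a numeric matrix with `labels`.
#' @param labels labels when `dataset` is a bare matrix.
#' @param inner_folds number of stratified inner folds (default 3).
#' @param base_classifier `"knn"` (default) or a registered classifier name.
#' @param knn_k neighbour count for the default base classifier.
#' @param seed integer seed for the fold split.
#' @return accuracy percentage in [0, 100].
#' @export
fitness <- function(mask, dataset, labels = NULL, inner_folds = 3L,
                    base_classifier = "knn", knn_k = 5L, seed = 1L) {
  if (inherits(dataset, "labeled_dataset")) {
    X <- dataset$features; y <- dataset$labels
  } else {
    X <- as.matrix(dataset); y <- as.integer(labels)
  }
  s <- rng_stream(seed, "fitness")
  mask <- as.integer(mask != 0)
  if (sum(mask) == 0L) {
    cors <- suppressWarnings(abs(stats::cor(X, y))); cors[is.na(cors)] <- 0
    mask[which.max(cors)] <- 1L
  }
  fold <- make_stratified_folds(y, inner_folds, s)
  if (identical(base_classifier, "knn")) {
    return(knn_cv_fitness_cpp(X, mask, fold, y, as.integer(knn_k),
                              as.integer(inner_folds)))
  }
  sel <- which(mask == 1L)
  accs <- vapply(seq_len(inner_folds), function(sf) {
    tr <- fold != sf; te <- !tr
    mdl <- fit_classifier(base_classifier, X[tr, sel, drop = FALSE], y[tr],
                          stream = substream(s, paste0("base", sf)))
    pred <- predict(mdl, X[te, sel, drop = FALSE])
    100 * mean(pred == y[te])
  }, numeric(1L))
  mean(accs)
}
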