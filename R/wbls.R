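#' Weighted broad learning system
#'
#' A flat network: `n_windows` groups of random linear feature nodes and one
#' group of tanh enhancement nodes, concatenated into the state matrix
#' `U = [Jn | Em]` that feeds a weighted ridge-regression output layer.
#' Class imbalance is countered by per-sample balance weights: samples of
#' classes larger than the mean class size get weight `epsilon/(class size)`,
#' others `1/(class size)`, so minority samples always carry the larger
#' per-sample weight (at `epsilon = 1` every class gets the plain `1/size`
#' balance). Optional per-class misclassification costs and external
#' per-sample weights (used by boosting) multiply into the same diagonal.
#' The output weights solve `(lambda*I + U'VU) W = U'VQ` in closed form,
#' with `Q` one-hot targets.
#'
#' @param features numeric matrix (samples x features).
#' @param labels integer class labels, coded 0..L-1.
#' @param n_windows number of feature-node mapping windows (default 10).
#' @param nodes_per_window linear nodes per window (default 10).
#' @param m_enhance enhancement node count (default 100).
#' @param lambda ridge regularization (> 0, default 2^-10).
#' @param epsilon majority-class balance weight in (0, 1] (default 0.5).
#' @param cost optional per-class misclassification costs (length L);
#'   default all ones.
#' @param shrink enhancement input scale (default 0.8).
#' @param sample_weights optional external per-sample weights.
#' @param stream an [rng_stream()] generating the frozen random fields.
#' @return Object of class `wbls_model`.
#' @export
wbls_fit <- function(features, labels, n_windows = 10L, nodes_per_window = 10L,
                     m_enhance = 100L, lambda = 2^-10, epsilon = 0.5,
                     cost = NULL, shrink = 0.8, sample_weights = NULL,
                     stream = rng_stream(1L, "wbls")) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must lie in (0, 1]", call. = FALSE)
  X <- as.matrix(features)
  y <- as.integer(labels)
  classes <- sort(unique(y))
  L <- length(classes)
  n <- nrow(X); p <- ncol(X)
  nm <- minmax_normalize_fit_apply(X)
  Xn <- cbind(nm$normalized, 1)           # bias column for the random maps

  We <- lapply(seq_len(n_windows), function(i)
    matrix(stream_runif(stream, (p + 1L) * nodes_per_window, -1, 1),
           p + 1L, nodes_per_window))
  Jn <- do.call(cbind, lapply(We, function(Wi) Xn %*% Wi))
  Wk <- matrix(stream_runif(stream, (ncol(Jn) + 1L) * m_enhance, -1, 1),
               ncol(Jn) + 1L, m_enhance)
  Em <- tanh(shrink * (cbind(Jn, 1) %*% Wk))
  U <- cbind(Jn, Em)

  cls_idx <- match(y, classes)
  sizes <- tabulate(cls_idx, L)
  Z <- ifelse(sizes[cls_idx] > mean(sizes), epsilon / sizes[cls_idx],
              1 / sizes[cls_idx])
  if (is.null(cost)) cost <- rep(1, L)
  V <- Z * cost[cls_idx]
  if (!is.null(sample_weights)) V <- V * sample_weights / mean(sample_weights)

  Q <- matrix(0, n, L)
  Q[cbind(seq_len(n), cls_idx)] <- 1
  W <- solve(diag(lambda, ncol(U)) + crossprod(U, U * V), crossprod(U, Q * V))

  structure(list(We = We, Wk = Wk, W = W, shrink = shrink,
                 norm = nm, classes = classes, Z = Z, V = V,
                 n_windows = n_windows, nodes_per_window = nodes_per_window,
                 m_enhance = m_enhance, lambda = lambda, epsilon = epsilon),
            class = "wbls_model")
}

wbls_state <- function(object, X) {
  Xn <- cbind(apply_minmax(X, object$norm$min, object$norm$max), 1)
  Jn <- do.call(cbind, lapply(object$We, function(Wi) Xn %*% Wi))
  Em <- tanh(object$shrink * (cbind(Jn, 1) %*% object$Wk))
  cbind(Jn, Em)
}

#' @export
#' @rdname wbls_fit
#' @param object fitted `wbls_model`.
#' @param newdata matrix of new samples.
#' @param type `"class"`, `"prob"` (softmax over class scores) or `"score"`.
#' @param ... unused.
predict.wbls_model <- function(object, newdata, type = "class", ...) {
  S <- wbls_state(object, newdata) %*% object$W
  colnames(S) <- as.character(object$classes)
  if (type == "score") return(S)
  P <- exp(S - apply(S, 1L, max))
  P <- P / rowSums(P)
  if (type == "prob") return(P)
  object$classes[max.col(S, ties.method = "first")]
}

#' @export
print.wbls_model <- function(x, ...) {
  cat(sprintf("<wbls_model: %dx%d feature nodes + %d enhancement nodes, lambda %g>\n",
              x$n_windows, x$nodes_per_window, x$m_enhance, x$lambda))
  invisible(x)
}

#' HWBLSA: real-valued boosting of weighted broad learning systems
#'
#' Multiclass real-boosting with WBLS base learners. Each round fits a WBLS
#' under the current sample weights (folded into the WBLS per-sample
#' diagonal), converts its class probabilities (floored at 1e-10) into
#' zero-sum stage scores `h_l = (L-1)*(log P_l - mean_l log P_l)`, and
#' updates the sample weights with exponential loss on symmetric simplex
#' label codes. The final label is the argmax of the summed stage scores.
#' Round weights `alpha_m = 0.5*log((1-e)/e) + log(L-1)` are recorded; at
#' L = 2 they reduce to the classic Adaboost form.
#'
#' @param features,labels training data; labels coded 0..L-1.
#' @param M_rounds boosting rounds (default 10).
#' @param wbls_params named list of [wbls_fit()] overrides.
#' @param stream an [rng_stream()].
#' @return Object of class `hwblsa_model`.
#' @export
hwblsa_fit <- function(features, labels, M_rounds = 10L, wbls_params = list(),
                       stream = rng_stream(1L, "hwblsa")) {
  if (M_rounds < 1L) stop("M_rounds must be >= 1", call. = FALSE)
  X <- as.matrix(features)
  y <- as.integer(labels)
  classes <- sort(unique(y))
  L <- length(classes)
  n <- nrow(X)
  cls_idx <- match(y, classes)
  codes <- matrix(-1 / (L - 1), n, L)     # symmetric simplex label codes
  codes[cbind(seq_len(n), cls_idx)] <- 1

  w <- rep(1 / n, n)
  models <- list(); alphas <- numeric(0); errors <- numeric(0)
  skipped <- 0L
  for (m in seq_len(M_rounds)) {
    args <- c(list(features = X, labels = y, sample_weights = w,
                   stream = substream(stream, paste0("wbls", m))),
              wbls_params)
    base <- do.call(wbls_fit, args)
    P <- predict(base, X, type = "prob")
    P[P < 1e-10] <- 1e-10
    pred <- classes[max.col(P, ties.method = "first")]
    e_m <- sum(w * (pred != y)) / sum(w)
    if (e_m >= (L - 1) / L) {             # no better than chance: skip round
      skipped <- skipped + 1L
      next
    }
    models[[length(models) + 1L]] <- base
    alphas <- c(alphas, 0.5 * log((1 - max(e_m, 1e-10)) / max(e_m, 1e-10)) +
                  log(L - 1))
    errors <- c(errors, e_m)
    w <- w * exp(-(L - 1) / L * rowSums(codes * log(P)))
    w <- w / sum(w)
    if (e_m == 0) break                   # perfect round: stop early
  }
  if (!length(models)) stop("hwblsa: no usable boosting round", call. = FALSE)
  structure(list(models = models, alphas = alphas, errors = errors,
                 classes = classes, L = L, skipped = skipped),
            class = "hwblsa_model")
}

#' Stage scores of one HWBLSA round
#'
#' Zero-sum transform of base-classifier probabilities:
#' `(L-1) * (log P_l - mean_l log P_l)`.
#' @param P probability matrix (rows sum to 1), floored at 1e-10.
#' @export
hwblsa_stage_scores <- function(P) {
  P[P < 1e-10] <- 1e-10
  lp <- log(P)
  (ncol(P) - 1) * (lp - rowMeans(lp))
}

#' @export
#' @rdname hwblsa_fit
#' @param object fitted `hwblsa_model`.
#' @param newdata matrix of new samples.
#' @param type `"class"`, `"prob"` or `"score"` (summed stage scores).
#' @param ... unused.
predict.hwblsa_model <- function(object, newdata, type = "class", ...) {
  Hsum <- 0
  for (base in object$models) {
    P <- predict(base, newdata, type = "prob")
    Hsum <- Hsum + hwblsa_stage_scores(P)
  }
  colnames(Hsum) <- as.character(object$classes)
  if (type == "score") return(Hsum)
  if (type == "prob") {
    S <- Hsum / (length(object$models) * max(object$L - 1, 1))
    P <- exp(S - apply(S, 1L, max))
    return(P / rowSums(P))
  }
  object$classes[max.col(Hsum, ties.method = "first")]
}

#' @export
print.hwblsa_model <- function(x, ...) {
  cat(sprintf("<hwblsa_model: %d rounds%s, %d classes>\n",
              length(x$models),
              if (x$skipped > 0L) sprintf(" (%d skipped)", x$skipped) else "",
              x$L))
  invisible(x)
}
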