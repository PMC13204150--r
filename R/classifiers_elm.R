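pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

elm_activation <- function(name) {
  switch(name,
    sigmoid = function(z) 1 / (1 + exp(-z)),
    tanh    = tanh,
    relu    = function(z) pmax(z, 0),
    stop(sprintf("unknown activation '%s'", name), call. = FALSE))
}

#' Extreme learning machine
#'
#' Single-hidden-layer network with random frozen input weights and biases
#' (uniform on [-1, 1]); only the output weights are learned, by a ridge (or
#' pseudoinverse, when `ridge = 0`) least-squares solve of the hidden-layer
#' system.
#'
#' @param features numeric matrix (samples x features).
#' @param targets numeric vector or matrix of training targets.
#' @param n_hidden hidden node count (default 100).
#' @param activation `"sigmoid"` (default), `"tanh"` or `"relu"`.
#' @param ridge ridge penalty on the output weights (default 1e-6; 0 gives
#'   the minimum-norm pseudoinverse solution).
#' @param weights optional non-negative per-sample weights: the output
#'   weights then solve the weighted ridge system (used by boosting).
#' @param stream an [rng_stream()] generating the frozen random layer.
#' @return Object of class `elm_model` with a [predict.elm_model()] method.
#' @export
elm_fit <- function(features, targets, n_hidden = 100L,
                    activation = "sigmoid", ridge = 1e-6, weights = NULL,
                    stream = rng_stream(1L, "elm")) {
  X <- as.matrix(features)
  Tm <- as.matrix(targets)
  if (n_hidden < 1L) stop("n_hidden must be >= 1", call. = FALSE)
  p <- ncol(X)
  W <- matrix(stream_runif(stream, p * n_hidden, -1, 1), p, n_hidden)
  b <- stream_runif(stream, n_hidden, -1, 1)
  act <- elm_activation(activation)
  H <- act(sweep(X %*% W, 2L, b, "+"))
  beta <- if (!is.null(weights)) {
    v <- weights / mean(weights)
    solve(crossprod(H, H * v) + diag(max(ridge, 1e-10), n_hidden),
          crossprod(H, Tm * v))
  } else if (ridge > 0) {
    solve(crossprod(H) + diag(ridge, n_hidden), crossprod(H, Tm))
  } else {
    pinv(H) %*% Tm
  }
  structure(list(W = W, b = b, beta = beta, activation = activation,
                 n_hidden = n_hidden, ridge = ridge),
            class = "elm_model")
}

#' @export
#' @rdname elm_fit
#' @param object fitted `elm_model`.
#' @param newdata matrix of new samples.
#' @param ... unused.
predict.elm_model <- function(object, newdata, ...) {
  act <- elm_activation(object$activation)
  H <- act(sweep(as.matrix(newdata) %*% object$W, 2L, object$b, "+"))
  H %*% object$beta
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model: %d hidden nodes, %s activation, ridge %g>\n",
              x$n_hidden, x$activation, x$ridge))
  invisible(x)
}

#' Min-max normalization fitted on training data
#'
#' Per-column `(x - min)/(max - min)`; constant columns map to 0. The fitted
#' bounds transform unseen data with clipping to [0, 1].
#'
#' @param features numeric matrix.
#' @return list with `normalized`, `min`, `max`.
#' @export
minmax_normalize_fit_apply <- function(features) {
  X <- as.matrix(features)
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rng <- hi - lo
  rng[rng < .Machine$double.eps] <- 1
  list(normalized = sweep(sweep(X, 2L, lo), 2L, rng, "/"), min = lo, max = hi)
}

apply_minmax <- function(X, lo, hi) {
  rng <- hi - lo
  rng[rng < .Machine$double.eps] <- 1
  out <- sweep(sweep(as.matrix(X), 2L, lo), 2L, rng, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Generic Adaboost over a weak-learner factory
#'
#' Classical discrete boosting with {0,1} class codes: per-round error
#' `e_i = |f(x_i) - y_i|`, proportional error `eps_t = sum(D * e)`, odds
#' `beta_t = eps/(1-eps)`, connection weight `w_t = 0.5*log(1/beta_t)` and
#' multiplicative distribution update `D * beta^(-e)` renormalized to the
#' simplex. A zero-error round caps the connection weight and stops early;
#' a round with `eps >= 0.5` is discarded and the distribution reset.
#'
#' @param features,labels training data, labels in {0, 1}.
#' @param base_fit function `(X, y, weights, stream) -> model`.
#' @param base_predict function `(model, X) -> {0,1} labels`.
#' @param T maximum boosting rounds.
#' @param resample if `TRUE` base learners see weight-resampled data;
#'   otherwise `base_fit` receives the weights directly.
#' @param stream an [rng_stream()].
#' @return Object of class `boosted_ensemble`.
#' @export
adaboost_fit <- function(features, labels, base_fit, base_predict, T = 10L,
                         resample = TRUE, stream = rng_stream(1L, "adaboost")) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  n <- nrow(X)
  if (T < 1L) stop("T must be >= 1", call. = FALSE)
  D <- rep(1 / n, n)                      # uniform initial distribution
  models <- list(); wts <- numeric(0)
  D_hist <- list()
  discarded <- 0L
  t <- 1L
  while (length(models) < T && t <= 2L * T) {
    t <- t + 1L
    sub <- substream(stream, paste0("round", t))
    uniform_D <- diff(range(D)) < 1e-15
    model <- if (resample && !uniform_D) {
      idx <- stream_sample(stream, n, n, replace = TRUE, prob = D)
      base_fit(X[idx, , drop = FALSE], y[idx], NULL, sub)
    } else {
      # a uniform distribution needs no resampling: use the full data
      base_fit(X, y, if (resample) NULL else D, sub)
    }
    f <- as.integer(base_predict(model, X))
    e <- pmin(pmax(abs(f - y), 0), 1)
    eps <- sum(D * e)
    if (eps >= 0.5) {                     # unusable round: reset and retry
      discarded <- discarded + 1L
      D <- rep(1 / n, n)
      next
    }
    beta <- max(eps / (1 - eps), 1e-10)   # log guard for eps == 0
    models[[length(models) + 1L]] <- model
    wts <- c(wts, 0.5 * log(1 / beta))
    D <- D * beta^(-e)
    D <- D / sum(D)
    D_hist[[length(D_hist) + 1L]] <- D
    if (eps == 0) break                   # perfect learner: stop boosting
  }
  structure(list(models = models, weights = wts, base_predict = base_predict,
                 T = length(models), discarded = discarded,
                 D_history = D_hist, flavor = "adaboost"),
            class = "boosted_ensemble")
}

#' @export
print.boosted_ensemble <- function(x, ...) {
  cat(sprintf("<boosted_ensemble %s: %d rounds%s>\n", x$flavor, x$T,
              if (x$discarded > 0L) sprintf(" (%d discarded)", x$discarded) else ""))
  invisible(x)
}

boost_score <- function(object, X) {
  F <- numeric(nrow(as.matrix(X)))
  for (t in seq_along(object$models)) {
    F <- F + object$weights[t] * as.numeric(object$base_predict(object$models[[t]], X))
  }
  F / sum(object$weights)                 # in [0,1]: weighted vote for class 1
}

#' @export
#' @rdname adaboost_fit
#' @param object fitted `boosted_ensemble`.
#' @param newdata matrix of new samples.
#' @param type `"class"` for labels, `"prob"` for a two-column score matrix.
#' @param ... unused.
predict.boosted_ensemble <- function(object, newdata, type = "class", ...) {
  if (!is.null(object$norm)) {
    newdata <- apply_minmax(newdata, object$norm$min, object$norm$max)
  }
  s <- boost_score(object, newdata)
  if (type == "prob") return(cbind(`0` = 1 - s, `1` = s))
  as.integer(s >= 0.5)                    # threshold at the class-code midpoint
}

#' ELM-Adaboost hybrid classifier
#'
#' Min-max normalizes the features, then boosts extreme learning machines.
#' By default the boosting distribution enters each base ELM through a
#' weighted least-squares solve (deterministic given the stream); with
#' `resample = TRUE` base ELMs instead see weight-resampled data.
#'
#' @param features,labels training data, labels in {0, 1}.
#' @param T boosting rounds (default 10).
#' @param n_hidden hidden nodes per ELM (default 100).
#' @param ridge ELM ridge penalty.
#' @param resample use weight-resampling instead of weighted least squares.
#' @param stream an [rng_stream()].
#' @return A `boosted_ensemble` whose base models are [elm_fit()] networks
#'   on signed targets.
#' @export
elm_adaboost_fit <- function(features, labels, T = 10L, n_hidden = 100L,
                             ridge = 1e-6, resample = FALSE,
                             stream = rng_stream(1L, "elm_adaboost")) {
  nm <- minmax_normalize_fit_apply(features)
  base_fit <- function(X, y, w, s) {
    elm_fit(X, 2 * y - 1, n_hidden = n_hidden, ridge = ridge, weights = w,
            stream = s)
  }
  base_predict <- function(model, X) as.integer(predict(model, X) > 0)
  fit <- adaboost_fit(nm$normalized, labels, base_fit, base_predict,
                      T = T, resample = resample, stream = stream)
  fit$norm <- nm
  fit$flavor <- "elm_adaboost"
  fit
}
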