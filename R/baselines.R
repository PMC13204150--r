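#' Soft-voting committee of four conventional classifiers
#'
#' Multinomial logistic regression (iteration cap 500), polynomial-kernel
#' SVM with `C = 2` (probability-calibrated), a 250-tree random forest, and
#' 5-nearest-neighbours, trained on the same data; class probabilities are
#' averaged with equal weights and the label is the argmax. A base model
#' that fails to fit is excluded from the average with a warning.
#'
#' @param features,labels training data, labels in {0, 1}.
#' @param svm_cost SVM cost parameter (default 2).
#' @param rf_trees random forest size (default 250).
#' @param knn_k neighbour count (default 5).
#' @param maxit logistic-regression iteration cap (default 500).
#' @param stream an [rng_stream()].
#' @return Object of class `soft_vote_model`.
#' @export
soft_vote_fit <- function(features, labels, svm_cost = 2, rf_trees = 250L,
                          knn_k = 5L, maxit = 500L,
                          stream = rng_stream(1L, "soft_vote")) {
  X <- as.matrix(features)
  colnames(X) <- sprintf("x%03d", seq_len(ncol(X)))
  yf <- factor(labels, levels = c(0L, 1L))
  df <- data.frame(X, .y = yf)
  fits <- list()
  try_fit <- function(name, expr) {
    out <- tryCatch(stream_eval(stream, expr), error = function(e) {
      warning(sprintf("soft_vote: base model '%s' failed (%s), excluded",
                      name, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(out)) fits[[name]] <<- out
  }
  try_fit("logistic", nnet::multinom(.y ~ ., data = df, maxit = maxit,
                                     trace = FALSE))
  try_fit("svm", e1071::svm(X, yf, kernel = "polynomial", cost = svm_cost,
                            probability = TRUE))
  try_fit("rf", randomForest::randomForest(X, yf, ntree = rf_trees))
  fits$knn <- list(X = X, y = as.integer(labels), k = knn_k)
  structure(list(fits = fits, feature_names = colnames(X)),
            class = "soft_vote_model")
}

base_probs <- function(name, fit, X) {
  switch(name,
    logistic = {
      p1 <- as.numeric(stats::predict(fit, newdata = as.data.frame(X),
                                      type = "probs"))
      cbind(1 - p1, p1)
    },
    svm = {
      pr <- attr(stats::predict(fit, X, probability = TRUE), "probabilities")
      cbind(pr[, "0"], pr[, "1"])
    },
    rf = {
      pr <- stats::predict(fit, X, type = "prob")
      cbind(pr[, "0"], pr[, "1"])
    },
    knn = knn_prob(fit$X, fit$y, X, fit$k))
}

knn_prob <- function(Xtr, ytr, Xte, k) {
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * tcrossprod(Xte, Xtr)
  k <- min(k, nrow(Xtr))
  p1 <- apply(d2, 1L, function(dr) mean(ytr[order(dr)[seq_len(k)]]))
  cbind(1 - p1, p1)
}

#' @export
#' @rdname soft_vote_fit
#' @param object fitted `soft_vote_model`.
#' @param newdata matrix of new samples.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
predict.soft_vote_model <- function(object, newdata, type = "class", ...) {
  X <- as.matrix(newdata)
  colnames(X) <- object$feature_names
  acc <- 0
  for (name in names(object$fits)) {
    acc <- acc + base_probs(name, object$fits[[name]], X)
  }
  P <- acc / length(object$fits)
  colnames(P) <- c("0", "1")
  if (type == "prob") return(P)
  as.integer(P[, 2L] > P[, 1L])
}

#' @export
print.soft_vote_model <- function(x, ...) {
  cat(sprintf("<soft_vote_model: %s>\n", paste(names(x$fits), collapse = " + ")))
  invisible(x)
}

## ---- classifier registry ---------------------------------------------

classifier_names <- function() {
  c("elm_adaboost", "cart_adaboost", "hwblsa", "soft_vote", "rf", "nbc",
    "wbls", "cart", "knn", "majority")
}

#' Fit a classifier by registry name
#'
#' Uniform contract over the classifier zoo: the six grid classifiers
#' (`elm_adaboost`, `cart_adaboost`, `hwblsa`, `soft_vote`, `rf`, `nbc`)
#' plus standalone building blocks (`wbls`, `cart`, `knn`, `majority`).
#' Every returned model supports `predict(model, X)` for labels and
#' `predict(model, X, type = "prob")` for class probabilities.
#'
#' @param name registered classifier name.
#' @param features,labels training data, labels in {0, 1}.
#' @param params named list of overrides passed to the underlying fitter.
#' @param stream an [rng_stream()].
#' @export
fit_classifier <- function(name, features, labels, params = list(),
                           stream = rng_stream(1L, paste0("clf/", name))) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  switch(name,
    elm_adaboost = do.call(elm_adaboost_fit,
                           c(list(X, y, stream = stream), params)),
    cart_adaboost = do.call(cart_adaboost_fit,
                            c(list(X, y, stream = stream), params)),
    hwblsa = do.call(hwblsa_fit, c(list(X, y, stream = stream), params)),
    wbls = do.call(wbls_fit, c(list(X, y, stream = stream), params)),
    cart = do.call(cart_fit, c(list(X, y), params)),
    soft_vote = do.call(soft_vote_fit, c(list(X, y, stream = stream), params)),
    rf = {
      Xn <- X; colnames(Xn) <- sprintf("x%03d", seq_len(ncol(X)))
      fit <- stream_eval(stream, randomForest::randomForest(
        Xn, factor(y, levels = c(0L, 1L)),
        ntree = params$ntree %||% 250L))
      structure(list(fit = fit, names = colnames(Xn)), class = "rf_wrap")
    },
    nbc = {
      fit <- e1071::naiveBayes(X, factor(y, levels = c(0L, 1L)))
      structure(list(fit = fit), class = "nbc_wrap")
    },
    knn = structure(list(X = X, y = y, k = params$k %||% 5L),
                    class = "knn_model"),
    majority = structure(list(p1 = mean(y)), class = "majority_model"),
    stop(sprintf("unknown classifier '%s'", name), call. = FALSE))
}

#' @export
predict.rf_wrap <- function(object, newdata, type = "class", ...) {
  X <- as.matrix(newdata); colnames(X) <- object$names
  if (type == "prob") {
    pr <- stats::predict(object$fit, X, type = "prob")
    return(cbind(`0` = pr[, "0"], `1` = pr[, "1"]))
  }
  as.integer(as.character(stats::predict(object$fit, X)))
}

#' @export
predict.nbc_wrap <- function(object, newdata, type = "class", ...) {
  X <- as.matrix(newdata)
  if (type == "prob") {
    pr <- stats::predict(object$fit, X, type = "raw")
    return(cbind(`0` = pr[, "0"], `1` = pr[, "1"]))
  }
  as.integer(as.character(stats::predict(object$fit, X)))
}

#' @export
predict.knn_model <- function(object, newdata, type = "class", ...) {
  P <- knn_prob(object$X, object$y, as.matrix(newdata), object$k)
  colnames(P) <- c("0", "1")
  if (type == "prob") return(P)
  as.integer(P[, 2L] > 0.5)
}

#' @export
predict.majority_model <- function(object, newdata, type = "class", ...) {
  n <- nrow(as.matrix(newdata))
  if (type == "prob")
    return(cbind(`0` = rep(1 - object$p1, n), `1` = rep(object$p1, n)))
  rep(as.integer(object$p1 >= 0.5), n)
}
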