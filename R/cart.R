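#' Gini impurity and split gain
#'
#' `gini()` is the node impurity `1 - sum(p_c^2)` with (optionally weighted)
#' class proportions; `gini_gain()` is the impurity decrease of a binary
#' split, `GI(S) - W_L*GI(S_L) - W_R*GI(S_R)`.
#'
#' @param labels class labels of the node's samples.
#' @param weights optional non-negative per-sample weights.
#' @export
gini <- function(labels, weights = NULL) {
  if (length(labels) == 0L) stop("empty subset", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(labels))
  tot <- sum(weights)
  if (tot <= 0) return(0)
  pc <- tapply(weights, labels, sum) / tot
  1 - sum(pc^2)
}

#' @rdname gini
#' @param left logical vector: `TRUE` for samples sent to the left child.
#' @export
gini_gain <- function(labels, left, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(labels))
  if (all(left) || !any(left)) stop("split leaves one side empty", call. = FALSE)
  wl <- sum(weights[left]) / sum(weights)
  gini(labels, weights) - wl * gini(labels[left], weights[left]) -
    (1 - wl) * gini(labels[!left], weights[!left])
}

# Best threshold split of one node, by exhaustive scan over midpoints of
# consecutive distinct values per feature, maximizing weighted Gini decrease.
best_split <- function(X, y, w, min_leaf) {
  n <- length(y)
  parent_gini <- gini_node_fast(y, w)
  best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_)
  wtot <- sum(w)
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xv <- X[ord, j]; yv <- y[ord]; wv <- w[ord]
    cw1 <- cumsum(wv * yv)                # class-1 weight left of cut
    cw <- cumsum(wv)
    cut_ok <- which(diff(xv) > 0)         # split between distinct values
    if (!length(cut_ok)) next
    nl <- cut_ok
    cut_ok <- cut_ok[nl >= min_leaf & (n - nl) >= min_leaf]
    if (!length(cut_ok)) next
    wl <- cw[cut_ok]; wl1 <- cw1[cut_ok]
    wr <- wtot - wl; wr1 <- cw1[n] - wl1
    gl <- 1 - ((wl1 / wl)^2 + ((wl - wl1) / wl)^2)
    gr <- 1 - ((wr1 / wr)^2 + ((wr - wr1) / wr)^2)
    gain <- parent_gini - (wl / wtot) * gl - (wr / wtot) * gr
    gi <- which.max(gain)
    if (gain[gi] > best$gain + 1e-12) {
      best <- list(gain = gain[gi], feature = j,
                   threshold = (xv[cut_ok[gi]] + xv[cut_ok[gi] + 1L]) / 2)
    }
  }
  best
}

gini_node_fast <- function(y, w) {
  wtot <- sum(w)
  p1 <- sum(w * y) / wtot
  1 - (p1^2 + (1 - p1)^2)
}

#' Classification and regression tree (classification, Gini criterion)
#'
#' Recursive binary splitting maximizing the weighted Gini decrease;
#' leaves predict the (weighted) majority class. Supports per-sample weights
#' so it can serve as an Adaboost base learner without resampling.
#'
#' @param features numeric matrix.
#' @param labels labels in {0, 1}.
#' @param weights optional per-sample weights.
#' @param max_depth maximum tree depth (>= 1; a depth-1 tree is one split).
#' @param min_leaf minimum samples per leaf.
#' @return Object of class `cart_model`.
#' @export
cart_fit <- function(features, labels, weights = NULL, max_depth = 3L,
                     min_leaf = 1L) {
  if (max_depth < 1L) stop("max_depth must be >= 1", call. = FALSE)
  X <- as.matrix(features)
  y <- as.integer(labels)
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  grow <- function(idx, depth) {
    yy <- y[idx]; ww <- w[idx]
    p1 <- sum(ww * yy) / sum(ww)
    leaf <- list(leaf = TRUE, pred = as.integer(p1 >= 0.5), p1 = p1)
    if (depth > max_depth || length(idx) < 2L * min_leaf ||
        length(unique(yy)) == 1L) return(leaf)
    sp <- best_split(X[idx, , drop = FALSE], yy, ww, min_leaf)
    if (is.na(sp$feature) || sp$gain <= 0) return(leaf)
    goes_left <- X[idx, sp$feature] <= sp$threshold
    list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
         gain = sp$gain,
         left = grow(idx[goes_left], depth + 1L),
         right = grow(idx[!goes_left], depth + 1L))
  }
  structure(list(root = grow(seq_along(y), 1L), max_depth = max_depth,
                 min_leaf = min_leaf),
            class = "cart_model")
}

tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' @export
print.cart_model <- function(x, ...) {
  cat(sprintf("<cart_model: depth %d>\n", tree_depth(x$root)))
  invisible(x)
}

#' @export
#' @rdname cart_fit
#' @param object fitted `cart_model`.
#' @param newdata matrix of new samples.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
predict.cart_model <- function(object, newdata, type = "class", ...) {
  X <- as.matrix(newdata)
  p1 <- vapply(seq_len(nrow(X)), function(i) {
    node <- object$root
    while (!node$leaf) {
      node <- if (X[i, node$feature] <= node$threshold) node$left else node$right
    }
    node$p1
  }, numeric(1L))
  if (type == "prob") return(cbind(`0` = 1 - p1, `1` = p1))
  as.integer(p1 >= 0.5)
}

#' CART-Adaboost hybrid classifier
#'
#' Boosts weight-aware Gini trees; the boosting distribution is folded
#' directly into the weighted class proportions of each split (no
#' resampling).
#'
#' @param features,labels training data, labels in {0, 1}.
#' @param T boosting rounds (default 10).
#' @param max_depth,min_leaf tree shape limits for the base trees.
#' @param stream an [rng_stream()].
#' @return A `boosted_ensemble` of `cart_model` base learners.
#' @export
cart_adaboost_fit <- function(features, labels, T = 10L, max_depth = 3L,
                              min_leaf = 1L,
                              stream = rng_stream(1L, "cart_adaboost")) {
  base_fit <- function(X, y, w, s) cart_fit(X, y, w, max_depth, min_leaf)
  base_predict <- function(model, X) predict(model, X)
  fit <- adaboost_fit(features, labels, base_fit, base_predict, T = T,
                      resample = FALSE, stream = stream)
  fit$flavor <- "cart_adaboost"
  fit
}
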