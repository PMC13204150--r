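#' @useDynLib neuroboost, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Column standardization (population convention)
#'
#' Centers each column at its mean and scales to unit population variance
#' (divisor n). Constant columns are mapped to zeros with their SD recorded
#' as 1, so the transform never divides by zero.
#'
#' @param features numeric matrix with at least 2 rows.
#' @return list with `scaled` (transformed matrix), `mu`, `sigma`.
#' @export
standardize_fit_transform <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) < 2L) stop("standardization needs at least 2 samples", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sigma <- sqrt(colMeans(Xc^2))            # population (1/n) convention
  sigma[sigma < .Machine$double.eps^0.5] <- 1
  list(scaled = sweep(Xc, 2L, sigma, "/"), mu = mu, sigma = sigma)
}

apply_standardize <- function(X, mu, sigma) {
  sweep(sweep(as.matrix(X), 2L, mu), 2L, sigma, "/")
}

#' Gaussian (RBF) kernel Gram matrix
#'
#' Entries `exp(-gamma * ||a_i - b_j||^2)`; symmetric with unit diagonal
#' when both inputs coincide.
#'
#' @param features_a,features_b numeric matrices with matching column counts.
#' @param gamma positive kernel width parameter.
#' @export
gaussian_gram <- function(features_a, features_b, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a positive scalar", call. = FALSE)
  A <- as.matrix(features_a); B <- as.matrix(features_b)
  if (ncol(A) != ncol(B)) stop("column counts must match", call. = FALSE)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

extractor_names <- function() c("none", "pca", "kpls", "kriging", "isomap", "kmeans")

#' Fit a feature-extraction model
#'
#' Dispatches to one of the five train-then-transform schemes (or the
#' identity). All fitted statistics come from the training rows only;
#' [predict.extractor_model()] never re-estimates anything.
#'
#' @param name one of `"none"`, `"pca"`, `"kpls"`, `"kriging"`, `"isomap"`,
#'   `"kmeans"`.
#' @param features numeric training matrix.
#' @param labels 0/1 labels (used by KPLS only).
#' @param params named list of scheme parameters (see Details).
#' @param stream an [rng_stream()] (used by K-means seeding).
#' @details Scheme parameters and defaults: PCA `output_dim` (10); KPLS
#'   `b` latent components (10) and Gaussian kernel width `gamma`
#'   (1/n_features); kriging target grid size `m` (10), `length_scale` (0.5),
#'   `variance` (0.2), `nugget` (1e-8); Isomap neighbor count `k` (10) and
#'   `d_out` (10); K-means cluster count `k` (20) with `max_iter` (300).
#' @return An object of class `extractor_model`.
#' @export
fit_extractor <- function(name, features, labels = NULL, params = list(),
                          stream = rng_stream(1L, paste0("extract/", name))) {
  X <- as.matrix(features)
  # defaults adapt to small inputs; explicitly supplied values are
  # validated strictly by the per-scheme fitters
  model <- switch(name,
    none    = list(scheme = "none", output_dim = ncol(X)),
    pca     = pca_fit(X, params$output_dim %||%
                        min(10L, nrow(X), ncol(X))),
    kpls    = kpls_fit(X, labels, params$b %||% min(10L, nrow(X) - 1L),
                       params$gamma %||% (1 / ncol(X))),
    kriging = kriging_fit(X, params$m %||% 10L,
                          params$length_scale %||% 0.5,
                          params$variance %||% 0.2,
                          params$nugget %||% 1e-8),
    isomap  = isomap_fit(X, params$k %||% min(10L, nrow(X) - 1L),
                         params$d_out %||% min(10L, nrow(X))),
    kmeans  = kmeans_features_fit(X, params$k %||% min(20L, nrow(X)), stream,
                                  params$max_iter %||% 300L),
    stop(sprintf("unknown extractor '%s'", name), call. = FALSE))
  model$n_train_cols <- ncol(X)
  class(model) <- c(paste0("extractor_", model$scheme), "extractor_model")
  model
}

#' @export
print.extractor_model <- function(x, ...) {
  cat(sprintf("<extractor_model scheme=%s, output_dim=%d>\n",
              x$scheme, x$output_dim))
  invisible(x)
}

#' Apply a fitted extractor to new data
#'
#' @param object an `extractor_model` from [fit_extractor()].
#' @param newdata numeric matrix with the training column count.
#' @param ... unused.
#' @return Matrix with `object$output_dim` columns.
#' @export
predict.extractor_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_train_cols)
    stop(sprintf("expected %d columns, got %d", object$n_train_cols, ncol(X)),
         call. = FALSE)
  out <- switch(object$scheme,
    none    = X,
    pca     = pca_transform(object, X),
    kpls    = kpls_transform(object, X),
    kriging = kriging_transform(object, X),
    isomap  = isomap_transform(object, X),
    kmeans  = kmeans_features_transform(object, X))
  colnames(out) <- sprintf("%s%02d", substr(object$scheme, 1, 3),
                           seq_len(ncol(out)))
  out
}

## ---- PCA -------------------------------------------------------------

pca_fit <- function(X, output_dim) {
  output_dim <- as.integer(output_dim)
  d_max <- min(nrow(X), ncol(X))
  if (output_dim < 1L || output_dim > d_max)
    stop(sprintf("output_dim must lie in [1, %d]", d_max), call. = FALSE)
  st <- standardize_fit_transform(X)
  n <- nrow(X)
  Covn <- crossprod(st$scaled) / n         # population covariance
  eig <- eigen(Covn, symmetric = TRUE)
  C <- eig$vectors[, seq_len(output_dim), drop = FALSE]
  C <- fix_signs(C)
  list(scheme = "pca", mu = st$mu, sigma = st$sigma, components = C,
       eigenvalues = eig$values, output_dim = output_dim)
}

# deterministic eigenvector orientation: largest-|loading| entry positive
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

pca_transform <- function(model, X) {
  apply_standardize(X, model$mu, model$sigma) %*% model$components
}

## ---- KPLS ------------------------------------------------------------

kpls_fit <- function(X, labels, b, gamma) {
  if (is.null(labels)) stop("KPLS requires labels", call. = FALSE)
  n <- nrow(X)
  b <- as.integer(b)
  if (b < 1L || b > n - 1L)
    stop(sprintf("latent count b must lie in [1, %d]", n - 1L), call. = FALSE)
  st <- standardize_fit_transform(X)
  K <- gaussian_gram(st$scaled, st$scaled, gamma)
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H                       # double-centered training Gram
  Y <- matrix(labels - mean(labels), n, 1L)

  Tm <- matrix(0, n, b); Um <- matrix(0, n, b)
  Kw <- Kc; Yw <- Y
  for (a in seq_len(b)) {
    if (sum(Yw^2) < 1e-12) {
      # target residual exhausted: continue along the deflated Gram's
      # leading direction so the model always emits b score columns
      u <- eigen(Kw, symmetric = TRUE)$vectors[, 1L]
    } else {
      u <- Yw[, 1L]
    }
    u <- u / sqrt(sum(u^2))
    for (it in 1:100) {
      tt <- Kw %*% u
      tt <- tt / sqrt(sum(tt^2))
      cc <- crossprod(Yw, tt)
      if (sum(cc^2) < 1e-24) break          # Y-free direction: t is fixed
      u_new <- Yw %*% cc
      u_new <- u_new / sqrt(sum(u_new^2))
      if (sum((u_new - u)^2) < 1e-12) { u <- u_new; break }
      u <- u_new
    }
    tt <- Kw %*% u
    tt <- tt / sqrt(sum(tt^2))
    Tm[, a] <- tt; Um[, a] <- u
    P <- diag(n) - tcrossprod(tt)
    Kw <- P %*% Kw %*% P
    Yw <- Yw - tt %*% crossprod(tt, Yw)
  }
  proj <- Um %*% qr.solve(crossprod(Tm, Kc %*% Um), tol = 1e-12)
  list(scheme = "kpls", mu = st$mu, sigma = st$sigma, gamma = gamma,
       X_train = st$scaled, K_raw = K, scores = Tm, projection = proj,
       n_train = n, output_dim = b)
}

kpls_transform <- function(model, X) {
  Xs <- apply_standardize(X, model$mu, model$sigma)
  Kt <- gaussian_gram(Xs, model$X_train, model$gamma)
  n <- model$n_train
  H <- diag(n) - matrix(1 / n, n, n)
  # test-kernel centering with training statistics
  Ktc <- (Kt - matrix(1 / n, nrow(Kt), n) %*% model$K_raw) %*% H
  Ktc %*% model$projection
}

## ---- Kriging ---------------------------------------------------------

# Per-sample 1-D ordinary kriging: a sample's p feature values are treated
# as observations of a field at normalized index locations in [0,1] and
# kriged onto m equispaced target locations under a Gaussian covariance.
kriging_fit <- function(X, m, length_scale = 0.5, variance = 0.2,
                        nugget = 1e-8) {
  m <- as.integer(m)
  if (m < 1L) stop("grid size m must be >= 1", call. = FALSE)
  p <- ncol(X)
  if (p < 2L) stop("kriging needs at least 2 feature columns", call. = FALSE)
  obs <- seq(0, 1, length.out = p)
  tgt <- if (m == 1L) 0.5 else seq(0, 1, length.out = m)
  kfun <- function(d) variance * exp(-d^2 / (2 * length_scale^2))
  K <- kfun(abs(outer(obs, obs, "-"))) + diag(nugget, p)
  k0 <- kfun(abs(outer(obs, tgt, "-")))
  # ordinary-kriging system: unbiasedness row forces weights to sum to 1
  A <- rbind(cbind(K, 1), c(rep(1, p), 0))
  B <- rbind(k0, rep(1, m))
  sol <- solve(A, B)
  lambda <- sol[seq_len(p), , drop = FALSE]  # p x m weight matrix
  list(scheme = "kriging", weights = lambda, obs = obs, targets = tgt,
       length_scale = length_scale, variance = variance, nugget = nugget,
       output_dim = m)
}

kriging_transform <- function(model, X) {
  as.matrix(X) %*% model$weights
}

## ---- Isomap ----------------------------------------------------------

isomap_fit <- function(X, k, d_out) {
  k <- as.integer(k); d_out <- as.integer(d_out)
  n <- nrow(X)
  if (k < 1L) stop("neighbor count k must be >= 1", call. = FALSE)
  if (d_out < 1L || d_out > n)
    stop("d_out must lie in [1, n_train]", call. = FALSE)
  st <- standardize_fit_transform(X)
  D <- as.matrix(stats::dist(st$scaled))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:min(k + 1L, n)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)                       # symmetric kNN graph
  W <- D; W[!adj] <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    # bridge the two closest components by their shortest Euclidean edge
    best <- c(Inf, NA, NA)
    for (ca in seq_len(comp$no - 1L)) for (cb in (ca + 1L):comp$no) {
      ia <- which(comp$membership == ca); ib <- which(comp$membership == cb)
      sub <- D[ia, ib, drop = FALSE]
      w <- which.min(sub)
      if (sub[w] < best[1L]) {
        best <- c(sub[w], ia[(w - 1L) %% length(ia) + 1L],
                  ib[(w - 1L) %/% length(ia) + 1L])
      }
    }
    warning(sprintf("isomap: disconnected neighbor graph, bridging %d-%d",
                    best[2L], best[3L]), call. = FALSE)
    g <- igraph::add_edges(g, c(best[2L], best[3L]), weight = best[1L])
    comp <- igraph::components(g)
  }
  geo <- igraph::distances(g, weights = igraph::E(g)$weight)
  D2 <- geo^2
  J <- diag(n) - matrix(1 / n, n, n)
  Bmat <- -0.5 * J %*% D2 %*% J
  eig <- eigen((Bmat + t(Bmat)) / 2, symmetric = TRUE)
  pos <- which(eig$values > 1e-10)
  d_use <- min(d_out, length(pos))
  V <- fix_signs(eig$vectors[, seq_len(d_use), drop = FALSE])
  lam <- eig$values[seq_len(d_use)]
  emb <- V %*% diag(sqrt(lam), d_use)
  if (d_use < d_out) emb <- cbind(emb, matrix(0, n, d_out - d_use))
  list(scheme = "isomap", mu = st$mu, sigma = st$sigma, k = k,
       X_train = st$scaled, geo = geo, col_mean_D2 = colMeans(D2),
       V = V, lambda = lam, d_use = d_use, embedding = emb,
       output_dim = d_out)
}

isomap_transform <- function(model, X) {
  Xs <- apply_standardize(X, model$mu, model$sigma)
  n <- nrow(model$X_train)
  m <- nrow(Xs)
  d2x <- outer(rowSums(Xs^2), rowSums(model$X_train^2), "+") -
    2 * tcrossprod(Xs, model$X_train)
  d2x[d2x < 0] <- 0
  dx <- sqrt(d2x)
  out <- matrix(0, m, model$output_dim)
  scale_back <- sweep(model$V, 2L, sqrt(model$lambda), "/")
  for (i in seq_len(m)) {
    nn <- order(dx[i, ])[seq_len(min(model$k, n))]
    if (dx[i, nn[1L]] < 1e-12) {
      dg <- model$geo[nn[1L], ]             # exact match: reuse fitted geodesics
    } else {
      cand <- sweep(model$geo[nn, , drop = FALSE], 1L, dx[i, nn], "+")
      dg <- apply(cand, 2L, min)
    }
    y <- 0.5 * (model$col_mean_D2 - dg^2) %*% scale_back
    out[i, seq_len(model$d_use)] <- y
  }
  out
}

## ---- K-means distance features ---------------------------------------

kmeans_features_fit <- function(X, k, stream, max_iter = 300L) {
  k <- as.integer(k)
  n <- nrow(X)
  if (k < 1L || k > n) stop("cluster count k must lie in [1, n_train]", call. = FALSE)
  st <- standardize_fit_transform(X)
  Xs <- st$scaled
  # greedy farthest-point seeding from the stream
  centers <- matrix(0, k, ncol(Xs))
  first <- stream_sample(stream, n, 1L)
  centers[1L, ] <- Xs[first, ]
  if (k > 1L) {
    dmin <- colSums((t(Xs) - centers[1L, ])^2)
    for (h in 2L:k) {
      nxt <- which.max(dmin)
      centers[h, ] <- Xs[nxt, ]
      dmin <- pmin(dmin, colSums((t(Xs) - centers[h, ])^2))
    }
  }
  assign_prev <- rep(-1L, n)
  wss_trace <- numeric(0)      # within-cluster sum of squares (Lloyd objective)
  sd_trace <- numeric(0)       # summed plain distances, recorded alongside
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(Xs, centers)
    assign_cur <- max.col(-d2, ties.method = "first")
    # empty cluster: reseed at the point farthest from its nearest centroid
    for (h in which(tabulate(assign_cur, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(n), assign_cur)])
      centers[h, ] <- Xs[far, ]
      d2[, h] <- colSums((t(Xs) - centers[h, ])^2)
      assign_cur <- max.col(-d2, ties.method = "first")
    }
    dmin2 <- d2[cbind(seq_len(n), assign_cur)]
    wss_trace <- c(wss_trace, sum(dmin2))
    sd_trace <- c(sd_trace, sum(sqrt(pmax(dmin2, 0))))
    if (identical(assign_cur, assign_prev)) break
    assign_prev <- assign_cur
    for (h in seq_len(k)) {
      centers[h, ] <- colMeans(Xs[assign_cur == h, , drop = FALSE])
    }
  }
  list(scheme = "kmeans", mu = st$mu, sigma = st$sigma, centers = centers,
       k = k, assignment = assign_prev, wss_trace = wss_trace,
       sd_trace = sd_trace, output_dim = k)
}

dist2_to_centers <- function(X, centers) {
  d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * tcrossprod(X, centers)
  d2[d2 < 0] <- 0
  d2
}

kmeans_features_transform <- function(model, X) {
  Xs <- apply_standardize(X, model$mu, model$sigma)
  sqrt(dist2_to_centers(Xs, model$centers))
}
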