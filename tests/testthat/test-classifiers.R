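test_that("ELM output weights match an independent least-squares oracle", {
  set.seed(31)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- 2 * as.integer(X[, 1L] > 0) - 1
  m <- elm_fit(X, y, n_hidden = 20, ridge = 1e-6, stream = rng_stream(1, "e"))
  H <- 1 / (1 + exp(-sweep(X %*% m$W, 2L, m$b, "+")))
  beta_or <- solve(crossprod(H) + diag(1e-6, 20), crossprod(H, y))
  expect_equal(m$beta, beta_or, tolerance = 1e-8)
  # determinism under the same stream
  m2 <- elm_fit(X, y, n_hidden = 20, ridge = 1e-6, stream = rng_stream(1, "e"))
  expect_identical(m$beta, m2$beta)
})

test_that("an over-parameterized ELM interpolates its training targets", {
  set.seed(32)
  X <- matrix(rnorm(15 * 4), 15, 4)
  y <- rnorm(15)
  m <- elm_fit(X, y, n_hidden = 40, ridge = 0, stream = rng_stream(2, "e"))
  expect_lt(sum((predict(m, X) - y)^2), 1e-6)
})

test_that("Adaboost starts uniform, keeps weights on the simplex, and beats a lone stump", {
  set.seed(33)
  # 1-D threshold-learnable toy set with label noise
  x <- matrix(sort(runif(60)), ncol = 1L)
  y <- as.integer(x[, 1L] > 0.5)
  flip <- sample(60, 8)
  y[flip] <- 1L - y[flip]
  stump_fit <- function(X, yy, w, s) cart_fit(X, yy, w, max_depth = 1L)
  stump_pred <- function(m, X) predict(m, X)
  fit <- adaboost_fit(x, y, stump_fit, stump_pred, T = 15, resample = FALSE,
                      stream = rng_stream(3, "ada"))
  for (D in fit$D_history) {
    expect_equal(sum(D), 1)
    expect_true(all(D >= 0))
  }
  expect_true(all(is.finite(fit$weights)))
  # exhaustive stump oracle: best single threshold's training accuracy
  accs <- vapply(seq(0, 1, by = 0.005), function(th) {
    max(mean((x[, 1L] > th) == y), mean((x[, 1L] <= th) == y))
  }, numeric(1L))
  ens_acc <- mean(predict(fit, x) == y)
  expect_gte(ens_acc, max(accs))
})

test_that("min-max normalization maps to [0,1], guards constants, and clips unseen values", {
  nm <- minmax_normalize_fit_apply(matrix(c(2, 4, 6), 3, 1))
  expect_equal(nm$normalized[, 1L], c(0, 0.5, 1))
  cst <- minmax_normalize_fit_apply(matrix(5, 4, 1))
  expect_equal(cst$normalized[, 1L], rep(0, 4))
  set.seed(34)
  X <- matrix(rnorm(60), 20, 3)
  nm2 <- minmax_normalize_fit_apply(X)
  out <- neuroboost:::apply_minmax(matrix(c(100, -100, 0), 1, 3),
                                   nm2$min, nm2$max)
  expect_equal(out[1L, 1L], 1)
  expect_equal(out[1L, 2L], 0)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("a single-round ELM-Adaboost equals its lone base ELM and separable data is learned", {
  ds <- tiny_dataset(n0 = 40, n1 = 20, p = 6, k = 3, effect = 3, seed = 35)
  fit1 <- fit_classifier("elm_adaboost", ds$features, ds$labels,
                         params = list(T = 1L), stream = rng_stream(4, "ea"))
  expect_length(fit1$models, 1L)
  Xn <- neuroboost:::apply_minmax(ds$features, fit1$norm$min, fit1$norm$max)
  lone <- as.integer(predict(fit1$models[[1L]], Xn) > 0)
  expect_equal(predict(fit1, ds$features), lone)
  fit10 <- fit_classifier("elm_adaboost", ds$features, ds$labels,
                          stream = rng_stream(4, "ea"))
  expect_gte(100 * mean(predict(fit10, ds$features) == ds$labels), 99)
  # determinism
  fit10b <- fit_classifier("elm_adaboost", ds$features, ds$labels,
                           stream = rng_stream(4, "ea"))
  expect_identical(predict(fit10, ds$features), predict(fit10b, ds$features))
})

test_that("Gini impurity and the chosen CART split match exhaustive enumeration", {
  expect_equal(gini(c(1, 1, 1)), 0)
  expect_equal(gini(c(0, 0, 1, 1)), 0.5)
  expect_equal(gini_gain(c(0, 0, 1, 1), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_error(gini(integer(0)), "empty")
  expect_error(gini_gain(c(0, 1), c(TRUE, TRUE)), "empty")
  set.seed(36)
  X <- matrix(rnorm(20 * 3), 20, 3)
  y <- as.integer(X[, 2L] + 0.3 * rnorm(20) > 0)
  tree <- cart_fit(X, y, max_depth = 1L)
  # brute-force oracle over all features and thresholds
  best <- -Inf
  for (j in 1:3) {
    for (th in sort(unique(X[, j]))[-20]) {
      left <- X[, j] <= th
      if (any(left) && !all(left)) {
        g <- gini_gain(y, left)
        if (g > best) best <- g
      }
    }
  }
  expect_equal(tree$root$gain, best, tolerance = 1e-12)
})

test_that("CART learns 1-D separable data with a single split and boosting helps on noise", {
  x <- matrix(c(1:10), ncol = 1L)
  y <- as.integer(x[, 1L] > 5)
  tree <- cart_fit(x, y, max_depth = 5L)
  expect_equal(neuroboost:::tree_depth(tree$root), 1L)
  expect_equal(predict(tree, x), y)
  set.seed(37)
  X <- matrix(rnorm(80 * 4), 80, 4)
  yy <- as.integer(X[, 1L] + X[, 2L] + 0.8 * rnorm(80) > 0)
  single <- cart_fit(X, yy, max_depth = 2L)
  boosted <- fit_classifier("cart_adaboost", X, yy,
                            params = list(T = 20L, max_depth = 2L),
                            stream = rng_stream(5, "ca"))
  err_single <- mean(predict(single, X) != yy)
  err_boost <- mean(predict(boosted, X) != yy)
  expect_lte(err_boost, err_single)
})

test_that("WBLS balance weights follow the class-size rule and W solves the weighted ridge system", {
  ds <- tiny_dataset(n0 = 49, n1 = 13, p = 5, seed = 38)   # imbalanced
  m <- fit_classifier("wbls", ds$features, ds$labels,
                      params = list(epsilon = 0.5, n_windows = 3L,
                                    nodes_per_window = 4L, m_enhance = 10L),
                      stream = rng_stream(6, "w"))
  expect_true(all(m$Z[ds$labels == 0L] == 0.5 / 49))  # majority: epsilon/size
  expect_true(all(m$Z[ds$labels == 1L] == 1 / 13))    # minority: 1/size
  expect_gt(min(m$Z[ds$labels == 1L]), max(m$Z[ds$labels == 0L]))
  # independent dense solve of (lambda I + U'VU) W = U'VQ
  U <- neuroboost:::wbls_state(m, ds$features)
  Q <- cbind(1 - ds$labels, ds$labels)
  lamI <- diag(m$lambda, ncol(U))
  W_or <- solve(lamI + t(U) %*% diag(m$V) %*% U, t(U) %*% diag(m$V) %*% Q)
  expect_lt(max(abs(m$W - W_or)) / max(abs(W_or)), 1e-8)
})

test_that("a square invertible WBLS state interpolates one-hot targets as lambda vanishes", {
  set.seed(39)
  n <- 12
  # p+1 = 9 input dims so the 6 linear feature nodes are full rank and the
  # 12-column state matrix is invertible
  X <- matrix(rnorm(n * 8), n, 8)
  y <- rep(c(0L, 1L), each = n / 2)
  m <- wbls_fit(X, y, n_windows = 2L, nodes_per_window = 3L, m_enhance = 6L,
                lambda = 1e-12, epsilon = 1, stream = rng_stream(7, "w"))
  # balanced classes with epsilon = 1: both classes sized 6 > mean? no —
  # equal sizes mean no class exceeds the mean, so Z = 1/6 uniformly and
  # the system reduces to plain ridge
  expect_true(all(abs(m$Z - 1 / 6) < 1e-12))
  U <- neuroboost:::wbls_state(m, X)
  Q <- cbind(1 - y, y)
  expect_lt(max(abs(U %*% m$W - Q)), 1e-4)
})

test_that("HWBLSA stage scores are zero-sum and the L=2 round weight is the classic Adaboost alpha", {
  P <- matrix(c(0.9, 0.1, 0.3, 0.7, 0.5, 0.5), 3, 2, byrow = TRUE)
  h <- hwblsa_stage_scores(P)
  expect_lt(max(abs(rowSums(h))), 1e-12)
  # Eq-level identity: with two categories log(Cat - 1) = 0
  e <- 0.2
  alpha2 <- 0.5 * log((1 - e) / e) + log(2 - 1)
  expect_equal(alpha2, 0.5 * log((1 - e) / e))
})

test_that("HWBLSA matches an independent SAMME.R recipe on frozen base probabilities", {
  # freeze a set of per-round probability tables and compare the summed
  # stage scores with a from-scratch implementation of the real-boosting
  # recipe
  set.seed(40)
  n <- 30; L <- 3
  P_rounds <- lapply(1:4, function(m) {
    raw <- matrix(rexp(n * L), n, L)
    raw / rowSums(raw)
  })
  H_pkg <- Reduce(`+`, lapply(P_rounds, hwblsa_stage_scores))
  H_or <- 0
  for (P in P_rounds) {
    P[P < 1e-10] <- 1e-10
    lp <- log(P)
    H_or <- H_or + (L - 1) * (lp - rowMeans(lp) %*% t(rep(1, L)))
  }
  expect_equal(H_pkg, H_or, tolerance = 1e-12)
  expect_equal(apply(H_pkg, 1L, which.max), apply(H_or, 1L, which.max))
})

test_that("single-round HWBLSA labels equal the lone WBLS labels", {
  ds <- tiny_dataset(n0 = 30, n1 = 15, p = 5, seed = 41)
  hw <- hwblsa_fit(ds$features, ds$labels, M_rounds = 1L,
                   wbls_params = list(n_windows = 3L, nodes_per_window = 4L,
                                      m_enhance = 10L),
                   stream = rng_stream(8, "hw"))
  base <- hw$models[[1L]]
  expect_equal(predict(hw, ds$features), predict(base, ds$features))
})

test_that("soft voting averages the four base probability tables exactly", {
  ds <- tiny_dataset(n0 = 35, n1 = 15, p = 4, seed = 42)
  sv <- fit_classifier("soft_vote", ds$features, ds$labels,
                       stream = rng_stream(9, "sv"))
  P <- predict(sv, ds$features, type = "prob")
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  # duplicate-averaging oracle over the fitted bases
  Xn <- ds$features; colnames(Xn) <- sv$feature_names
  acc <- 0
  for (nm in names(sv$fits)) {
    acc <- acc + neuroboost:::base_probs(nm, sv$fits[[nm]], Xn)
  }
  expect_equal(unname(P), unname(acc / length(sv$fits)), tolerance = 1e-12)
  expect_equal(predict(sv, ds$features),
               as.integer(P[, 2L] > P[, 1L]))
})

test_that("baseline classifiers honor the common contract", {
  ds <- tiny_dataset(n0 = 30, n1 = 10, p = 4, seed = 43)
  for (nm in c("rf", "nbc", "knn", "majority")) {
    clf <- fit_classifier(nm, ds$features, ds$labels,
                          stream = rng_stream(10, nm))
    lab <- predict(clf, ds$features)
    expect_true(all(lab %in% c(0L, 1L)))
    P <- predict(clf, ds$features, type = "prob")
    expect_equal(dim(P), c(40L, 2L))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  }
  expect_equal(predict(fit_classifier("majority", ds$features, ds$labels),
                       ds$features),
               rep(0L, 40))
  expect_error(fit_classifier("nope", ds$features, ds$labels), "unknown")
})
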