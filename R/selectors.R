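selector_names <- function() {
  c("none", "cso", "rso", "cso_rso", "zoa", "gsa", "pso", "gsa_pso")
}

selector_defaults <- function(method) {
  common <- list(bounds = c(-5, 5), inner_folds = 3L, knn_k = 5L,
                 fitness_max_n = 300L)
  extra <- switch(method,
    cso     = list(pop = 100L, T = 200L, alpha = 0.5, lambda = 1.5, pa = 0.25),
    rso     = list(pop = 100L, T = 200L, A = NULL),
    cso_rso = list(pop = 100L, T = 200L, alpha = 0.5, lambda = 1.5, A = NULL),
    zoa     = list(pop = 50L,  T = 100L, C = 0.01),
    gsa     = list(pop = 100L, T = 200L, H0 = 100, beta = 20, eps = 1e-9),
    pso     = list(pop = 100L, T = 200L, theta = 0.5, b1 = 0.2, b2 = 0.4),
    gsa_pso = list(pop = 100L, T = 200L, theta = 0.5, b1 = 0.2, b2 = 0.4,
                   H0 = 100, beta = 20, eps = 1e-9),
    list())
  c(common, extra)
}

clamp <- function(M, bounds) {
  M[M < bounds[1L]] <- bounds[1L]
  M[M > bounds[2L]] <- bounds[2L]
  M
}

#' Initialize an optimizer state for wrapper feature selection
#'
#' Builds the shared population representation used by all seven selectors:
#' continuous positions in a box, sigmoid-binarized masks, cached wrapper
#' fitness, velocities for the kinematic family, and the best-so-far elite.
#'
#' @param features numeric matrix (samples x features).
#' @param labels 0/1 labels.
#' @param method selector name (see [select_features()]).
#' @param control named list of overrides for the method defaults.
#' @param stream an [rng_stream()] driving all randomness of the run.
#' @return An environment of class `optimizer_state`.
#' @export
init_optimizer <- function(features, labels, method, control = list(),
                           stream = rng_stream(1L, method)) {
  params <- utils::modifyList(selector_defaults(method), control)
  X <- as.matrix(features)
  p <- ncol(X)
  N <- params$pop
  st <- new.env(parent = emptyenv())
  st$method <- method
  st$params <- params
  st$stream <- stream
  st$p <- p
  st$t <- 0L
  st$T <- params$T
  st$fenv <- new_fitness_env(X, labels, substream(stream, "fitness"),
                             params$inner_folds, params$knn_k,
                             params$fitness_max_n)
  st$pos <- matrix(stream_runif(stream, N * p, params$bounds[1L],
                                params$bounds[2L]), N, p)
  st$vel <- matrix(0, N, p)
  if (method %in% c("rso", "cso_rso") && is.null(params$A)) {
    st$params$A <- stream_runif(stream, 1L)   # drawn once per run, U[0,1]
  }
  ev <- state_evaluate(st, st$pos)
  st$mask <- ev$mask
  st$fit <- ev$fit
  st$pbest_pos <- st$pos
  st$pbest_fit <- st$fit
  b <- which.max(st$fit)
  st$best <- list(position = st$pos[b, ], mask = st$mask[b, ],
                  fitness = st$fit[b])
  st$trace <- st$fit[b]
  class(st) <- "optimizer_state"
  st
}

state_evaluate <- function(st, positions) {
  M <- binarize(positions, st$fenv$repair_feature)
  st$fenv$repairs <- st$fenv$repairs + attr(M, "repairs")
  list(mask = M, fit = evaluate_masks(st$fenv, M))
}

update_best <- function(st) {
  b <- which.max(st$fit)
  if (st$fit[b] > st$best$fitness) {
    st$best <- list(position = st$pos[b, ], mask = st$mask[b, ],
                    fitness = st$fit[b])
  }
  st$trace <- c(st$trace, st$best$fitness)
  st$t <- st$t + 1L
  invisible(st)
}

#' @export
print.optimizer_state <- function(x, ...) {
  cat(sprintf("<optimizer_state %s: t=%d/%d, pop=%d, best=%.2f%%>\n",
              x$method, x$t, x$T, nrow(x$pos), x$best$fitness))
  invisible(x)
}

## ---- Cuckoo search ---------------------------------------------------

#' One iteration of cuckoo search
#'
#' Each nest proposes a Levy-flight move which is greedily compared against
#' a randomly chosen nest; then a fraction `pa` of the worst nests is
#' abandoned and re-drawn through a Heaviside-gated biased difference walk.
#'
#' @param st an `optimizer_state` from [init_optimizer()].
#' @return the updated state, invisibly.
#' @export
cso_iterate <- function(st) {
  p <- st$p; N <- nrow(st$pos); par <- st$params
  steps <- matrix(levy_step(st$stream, par$lambda, par$alpha, N * p), N, p)
  prop <- clamp(st$pos + steps, par$bounds)
  ev <- state_evaluate(st, prop)
  targets <- stream_sample(st$stream, N, N, replace = TRUE)
  moved <- rowSums(abs(prop - st$pos)) > 0
  for (k in seq_len(N)) {
    j <- targets[k]
    if (moved[k] && ev$fit[k] > st$fit[j]) {
      st$pos[j, ] <- prop[k, ]; st$mask[j, ] <- ev$mask[k, ]
      st$fit[j] <- ev$fit[k]
    }
  }
  n_ab <- round(par$pa * N)
  if (n_ab > 0L) {
    worst <- order(st$fit)[seq_len(n_ab)]
    gate <- (par$pa > stream_runif(st$stream, n_ab)) * 1   # Heaviside H(pa - eps)
    gamma_w <- stream_runif(st$stream, n_ab)
    d1 <- stream_sample(st$stream, N, n_ab, replace = TRUE)
    d2 <- stream_sample(st$stream, N, n_ab, replace = TRUE)
    walk <- st$pos[worst, , drop = FALSE] +
      (gamma_w * gate) * (st$pos[d1, , drop = FALSE] - st$pos[d2, , drop = FALSE])
    walk <- clamp(walk, par$bounds)
    evw <- state_evaluate(st, walk)
    st$pos[worst, ] <- walk; st$mask[worst, ] <- evw$mask
    st$fit[worst] <- evw$fit
  }
  update_best(st)
}

## ---- Rat swarm -------------------------------------------------------

#' One iteration of rat swarm optimization
#'
#' Each agent moves relative to the best agent: `R = Q*R_k + W*(R_s - R_k)`
#' with `Q = A - t*A/T` decaying linearly to zero and `W = 2*rand`, and the
#' candidate position is `R_s - R`, accepted greedily.
#'
#' @inheritParams cso_iterate
#' @export
rso_iterate <- function(st) {
  N <- nrow(st$pos); par <- st$params
  Q <- par$A - st$t * par$A / st$T
  W <- 2 * stream_runif(st$stream, N)
  bestm <- matrix(st$best$position, N, st$p, byrow = TRUE)
  R <- Q * st$pos + W * (bestm - st$pos)
  prop <- clamp(bestm - R, par$bounds)
  ev <- state_evaluate(st, prop)
  acc <- ev$fit > st$fit
  st$pos[acc, ] <- prop[acc, , drop = FALSE]
  st$mask[acc, ] <- ev$mask[acc, , drop = FALSE]
  st$fit[acc] <- ev$fit[acc]
  update_best(st)
}

## ---- Hybrid CSO-RSO --------------------------------------------------

cso_rso_iterate <- function(st) {
  p <- st$p; N <- nrow(st$pos); par <- st$params
  # CSO Levy proposal
  steps <- matrix(levy_step(st$stream, par$lambda, par$alpha, N * p), N, p)
  prop_c <- clamp(st$pos + steps, par$bounds)
  ev_c <- state_evaluate(st, prop_c)
  # RSO best-guided proposal on the same shared population
  Q <- par$A - st$t * par$A / st$T
  W <- 2 * stream_runif(st$stream, N)
  bestm <- matrix(st$best$position, N, p, byrow = TRUE)
  R <- Q * st$pos + W * (bestm - st$pos)
  prop_r <- clamp(bestm - R, par$bounds)
  ev_r <- state_evaluate(st, prop_r)
  # greedy hybridization: keep the better of the two proposals per agent
  use_c <- ev_c$fit >= ev_r$fit
  fit_p <- ifelse(use_c, ev_c$fit, ev_r$fit)
  acc <- fit_p > st$fit
  for (k in which(acc)) {
    if (use_c[k]) {
      st$pos[k, ] <- prop_c[k, ]; st$mask[k, ] <- ev_c$mask[k, ]
    } else {
      st$pos[k, ] <- prop_r[k, ]; st$mask[k, ] <- ev_r$mask[k, ]
    }
    st$fit[k] <- fit_p[k]
  }
  update_best(st)
}

## ---- Zebra optimization ----------------------------------------------

zoa_iterate <- function(st) {
  p <- st$p; N <- nrow(st$pos); par <- st$params
  # phase 1: foraging toward the pioneer zebra (current best)
  PZ <- matrix(st$best$position, N, p, byrow = TRUE)
  r1 <- matrix(stream_runif(st$stream, N * p), N, p)
  J1 <- round(1 + stream_runif(st$stream, N))
  prop <- clamp(st$pos + r1 * (PZ - J1 * st$pos), par$bounds)
  ev <- state_evaluate(st, prop)
  acc <- ev$fit > st$fit
  st$pos[acc, ] <- prop[acc, , drop = FALSE]
  st$mask[acc, ] <- ev$mask[acc, , drop = FALSE]
  st$fit[acc] <- ev$fit[acc]
  bi <- which.max(st$fit)
  if (st$fit[bi] > st$best$fitness)
    st$best <- list(position = st$pos[bi, ], mask = st$mask[bi, ],
                    fitness = st$fit[bi])
  # phase 2: defense — escape (S1, shrinking perturbation) or scare (S2)
  Ps <- stream_runif(st$stream, N)
  cmat <- matrix(stream_runif(st$stream, N * p), N, p)
  rz_idx <- stream_sample(st$stream, N, N, replace = TRUE)
  r2 <- matrix(stream_runif(st$stream, N * p), N, p)
  J2 <- round(1 + stream_runif(st$stream, N))
  s1 <- st$pos + par$C * (2 * cmat - 1) * (1 - st$t / st$T) * st$pos
  s2 <- st$pos + r2 * (st$pos[rz_idx, , drop = FALSE] - J2 * st$pos)
  prop2 <- s2
  prop2[Ps <= 0.5, ] <- s1[Ps <= 0.5, , drop = FALSE]
  prop2 <- clamp(prop2, par$bounds)
  ev2 <- state_evaluate(st, prop2)
  acc2 <- ev2$fit > st$fit
  st$pos[acc2, ] <- prop2[acc2, , drop = FALSE]
  st$mask[acc2, ] <- ev2$mask[acc2, , drop = FALSE]
  st$fit[acc2] <- ev2$fit[acc2]
  update_best(st)
}

## ---- Gravitational search --------------------------------------------

# Normalized masses from the fitness spread; uniform when the population
# is flat (best == worst).
gsa_masses <- function(fit) {
  worst <- min(fit); best <- max(fit)
  if (best - worst < .Machine$double.eps) return(rep(1 / length(fit), length(fit)))
  m <- (fit - worst) / (best - worst)
  m / sum(m)
}

#' Gravitational-constant decay schedule
#'
#' `H(t) = H0 * exp(-beta * t / T)`.
#' @param t iteration index.
#' @param T total iterations.
#' @param H0,beta schedule constants.
#' @export
gsa_gconst <- function(t, T, H0 = 100, beta = 20) H0 * exp(-beta * t / T)

gsa_acceleration <- function(st, draws = NULL) {
  N <- nrow(st$pos); par <- st$params
  G <- gsa_masses(st$fit)
  H <- gsa_gconst(st$t, st$T, par$H0, par$beta)
  E <- as.matrix(stats::dist(st$pos))
  Rnd <- if (!is.null(draws$force)) draws$force
         else matrix(stream_runif(st$stream, N * N), N, N)
  Wm <- Rnd * matrix(G, N, N, byrow = TRUE) / (E + par$eps)
  diag(Wm) <- 0
  H * (Wm %*% st$pos - rowSums(Wm) * st$pos)
}

#' One iteration of the gravitational search algorithm
#'
#' Masses from the population fitness spread, pairwise forces with stochastic
#' aggregation, inertial velocity update, position drift.
#'
#' @inheritParams cso_iterate
#' @param draws optional list of pre-drawn random fields (`force` N x N,
#'   `inertia` length N) used by exactness tests.
#' @export
gsa_iterate <- function(st, draws = NULL) {
  N <- nrow(st$pos); par <- st$params
  accel <- gsa_acceleration(st, draws)
  ri <- if (!is.null(draws$inertia)) draws$inertia else stream_runif(st$stream, N)
  st$vel <- ri * st$vel + accel
  st$pos <- clamp(st$pos + st$vel, par$bounds)
  ev <- state_evaluate(st, st$pos)
  st$mask <- ev$mask; st$fit <- ev$fit
  update_best(st)
}

## ---- Particle swarm --------------------------------------------------

#' One iteration of particle swarm optimization
#'
#' Velocity blends inertia, a cognitive pull toward each particle's personal
#' best and a social pull toward the global best.
#'
#' @inheritParams gsa_iterate
#' @export
pso_iterate <- function(st, draws = NULL) {
  N <- nrow(st$pos); p <- st$p; par <- st$params
  c1 <- if (!is.null(draws$c1)) draws$c1
        else matrix(stream_runif(st$stream, N * p), N, p)
  c2 <- if (!is.null(draws$c2)) draws$c2
        else matrix(stream_runif(st$stream, N * p), N, p)
  gbest <- matrix(st$best$position, N, p, byrow = TRUE)
  st$vel <- par$theta * st$vel + par$b1 * c1 * (st$pbest_pos - st$pos) +
    par$b2 * c2 * (gbest - st$pos)
  st$pos <- clamp(st$pos + st$vel, par$bounds)
  ev <- state_evaluate(st, st$pos)
  st$mask <- ev$mask; st$fit <- ev$fit
  imp <- st$fit > st$pbest_fit
  st$pbest_pos[imp, ] <- st$pos[imp, , drop = FALSE]
  st$pbest_fit[imp] <- st$fit[imp]
  update_best(st)
}

## ---- Hybrid GSA-PSO --------------------------------------------------

#' One iteration of the hybrid gravitational-search / particle-swarm update
#'
#' The GSA acceleration takes the cognitive slot of the PSO velocity update
#' and the global best takes the social slot:
#' `v <- theta*v + b1*c1*accel + b2*c2*(gbest - x)`.
#'
#' @inheritParams gsa_iterate
#' @export
gsa_pso_iterate <- function(st, draws = NULL) {
  N <- nrow(st$pos); p <- st$p; par <- st$params
  accel <- gsa_acceleration(st, draws)
  c1 <- if (!is.null(draws$c1)) draws$c1
        else matrix(stream_runif(st$stream, N * p), N, p)
  c2 <- if (!is.null(draws$c2)) draws$c2
        else matrix(stream_runif(st$stream, N * p), N, p)
  gbest <- matrix(st$best$position, N, p, byrow = TRUE)
  st$vel <- par$theta * st$vel + par$b1 * c1 * accel +
    par$b2 * c2 * (gbest - st$pos)
  st$pos <- clamp(st$pos + st$vel, par$bounds)
  ev <- state_evaluate(st, st$pos)
  st$mask <- ev$mask; st$fit <- ev$fit
  update_best(st)
}

## ---- Driver ----------------------------------------------------------

#' Run a biomimetic wrapper feature selector
#'
#' Optimizes a binary feature mask by cross-validated wrapper fitness using
#' one of seven population metaheuristics: cuckoo search (`"cso"`), rat swarm
#' (`"rso"`), their greedy hybrid (`"cso_rso"`), zebra optimization
#' (`"zoa"`), gravitational search (`"gsa"`), particle swarm (`"pso"`) or
#' the gravitational-search/particle-swarm hybrid (`"gsa_pso"`).
#' `"none"` returns the full mask without optimization.
#'
#' @param features numeric matrix (samples x features).
#' @param labels 0/1 class labels.
#' @param method selector name.
#' @param control named list overriding the method defaults (population
#'   size `pop`, iterations `T`, algorithm constants, `bounds`,
#'   `inner_folds`, `knn_k`, `fitness_max_n`).
#' @param seed integer master seed (ignored when `stream` is given).
#' @param stream optional [rng_stream()].
#' @return An object of class `feature_selection`: `mask`, `indices`,
#'   `fitness`, per-iteration best-fitness `trace`, evaluation and repair
#'   counts.
#' @export
select_features <- function(features, labels, method = "cso_rso",
                            control = list(), seed = 1L, stream = NULL) {
  if (!method %in% selector_names())
    stop(sprintf("unknown selector '%s'", method), call. = FALSE)
  X <- as.matrix(features)
  if (method == "none") {
    mask <- rep(1L, ncol(X))
    return(structure(list(method = "none", mask = mask,
                          indices = seq_len(ncol(X)),
                          fitness = NA_real_, trace = numeric(0),
                          evals = 0L, repairs = 0L),
                     class = "feature_selection"))
  }
  if (is.null(stream)) stream <- rng_stream(seed, paste0("select/", method))
  st <- init_optimizer(X, labels, method, control, stream)
  step <- switch(method, cso = cso_iterate, rso = rso_iterate,
                 cso_rso = cso_rso_iterate, zoa = zoa_iterate,
                 gsa = gsa_iterate, pso = pso_iterate,
                 gsa_pso = gsa_pso_iterate)
  while (st$t < st$T) step(st)
  structure(list(method = method, mask = st$best$mask,
                 indices = which(st$best$mask == 1L),
                 fitness = st$best$fitness, trace = st$trace,
                 evals = st$fenv$evals, repairs = st$fenv$repairs,
                 control = st$params),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection %s: %d features, fitness %.2f%%, %d evaluations>\n",
              x$method, sum(x$mask), x$fitness, x$evals))
  invisible(x)
}

#' @export
plot.feature_selection <- function(x, ...) {
  plot(seq_along(x$trace) - 1L, x$trace, type = "s",
       xlab = "iteration", ylab = "best fitness (%)",
       main = sprintf("%s best-so-far fitness", x$method), ...)
  invisible(x)
}
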