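sel_data <- function(seed = 21) {
  generate_dataset(generator_spec(40, 20, n_features = 10, n_informative = 3,
                                  effect_size = 2, seed = seed))
}

small_ctl <- function(...) {
  utils::modifyList(list(pop = 12L, T = 8L), list(...))
}

test_that("binarization follows the sign rule, repairs empty masks, and is monotone", {
  expect_equal(as.integer(binarize(c(-1, 0.2, 3))), c(0L, 1L, 1L))
  rep_mask <- binarize(rep(-5, 6), repair_feature = 4L)
  expect_equal(as.integer(rep_mask), c(0L, 0L, 0L, 1L, 0L, 0L))
  expect_equal(attr(rep_mask, "repairs"), 1L)
  set.seed(1)
  for (i in 1:50) {
    x <- rnorm(8)
    m1 <- as.integer(binarize(x))
    j <- sample(8, 1L)
    x2 <- x; x2[j] <- x2[j] + runif(1, 0, 3)
    m2 <- as.integer(binarize(x2))
    expect_gte(m2[j], m1[j])        # raising a coordinate never clears its bit
  }
})

test_that("Levy steps scale with alpha, are deterministic, and are heavy-tailed", {
  s <- rng_stream(3, "levy")
  expect_equal(levy_step(s, alpha = 0, dim = 10), rep(0, 10))
  a <- levy_step(rng_stream(5, "levy"), dim = 100)
  b <- levy_step(rng_stream(5, "levy"), dim = 100)
  expect_identical(a, b)
  expect_error(levy_step(s, lambda = 1), "lambda")
  expect_error(levy_step(s, lambda = 3.5), "lambda")
  # tail exponent: survival log-log slope near -1.5 over t in [10, 1000]
  draws <- abs(levy_step(rng_stream(11, "levy"), lambda = 1.5, alpha = 1,
                         dim = 1e6))
  ts <- 10^seq(1, 3, length.out = 12)
  surv <- vapply(ts, function(t) mean(draws > t), numeric(1L))
  slope <- coef(lm(log(surv) ~ log(ts)))[2L]
  expect_lt(abs(slope + 1.5), 0.5)
})

test_that("wrapper fitness equals an independent evaluation loop and hits its limits", {
  ds <- sel_data()
  mask <- rep(1L, 10)
  got <- fitness(mask, ds, inner_folds = 3, seed = 7)
  # duplicate-implementation oracle: plain R loop over the same folds
  s <- rng_stream(7, "fitness")
  fold <- make_stratified_folds(ds$labels, 3, s)
  accs <- vapply(1:3, function(sf) {
    tr <- fold != sf
    pr <- apply(ds$features[!tr, , drop = FALSE], 1L, function(x) {
      d2 <- colSums((t(ds$features[tr, ]) - x)^2)
      as.integer(mean(ds$labels[tr][order(d2)[1:5]]) > 0.5)
    })
    100 * mean(pr == ds$labels[!tr])
  }, numeric(1L))
  expect_equal(got, mean(accs))
  # perfectly separable data with the informative mask reaches 100
  sep <- generate_dataset(generator_spec(30, 30, n_features = 6,
                                         n_informative = 2, effect_size = 10,
                                         seed = 3))
  m <- as.integer(seq_len(6) %in% attr(sep, "informative"))
  expect_equal(fitness(m, sep, seed = 1), 100)
})

test_that("null-effect fitness stays within binomial noise of the majority rate", {
  ds <- generate_dataset(generator_spec(150, 50, n_features = 8,
                                        n_informative = 0, effect_size = 0,
                                        seed = 17))
  f <- fitness(rep(1L, 8), ds, seed = 5)
  maj <- 75
  sigma <- 100 * sqrt(0.75 * 0.25 / 200)
  expect_lt(abs(f - maj), 4 * sigma)
})

test_that("null dynamics leave cuckoo search unchanged", {
  ds <- sel_data()
  st <- init_optimizer(ds$features, ds$labels, "cso",
                       small_ctl(alpha = 0, pa = 0),
                       rng_stream(2, "cso"))
  pos0 <- st$pos; fit0 <- st$fit
  cso_iterate(st)
  expect_identical(st$pos, pos0)
  expect_identical(st$fit, fit0)
})

test_that("rat swarm position update collapses onto the best agent at the decay endpoint", {
  ds <- sel_data()
  st <- init_optimizer(ds$features, ds$labels, "rso", small_ctl(A = 0.8),
                       rng_stream(3, "rso"))
  st$t <- st$T                      # Q = A - T*A/T = 0
  # place one agent exactly at the best: its W-term vanishes and the
  # proposal is the best position itself
  st$pos[1L, ] <- st$best$position
  Q <- st$params$A - st$t * st$params$A / st$T
  expect_equal(Q, 0)
  prop1 <- st$best$position - (Q * st$pos[1L, ] + 1.3 * (st$best$position - st$pos[1L, ]))
  expect_equal(prop1, st$best$position)
})

test_that("all position updates respect the search bounds", {
  ds <- sel_data()
  for (m in c("cso", "rso", "zoa", "gsa", "pso", "gsa_pso")) {
    fs <- select_features(ds$features, ds$labels, m,
                          small_ctl(bounds = c(-2, 2)), seed = 4)
    expect_true(all(abs(fs$trace) <= 100))
  }
  st <- init_optimizer(ds$features, ds$labels, "pso",
                       small_ctl(bounds = c(-1, 1)), rng_stream(5, "pso"))
  for (i in 1:5) pso_iterate(st)
  expect_true(all(st$pos >= -1 & st$pos <= 1))
})

test_that("ZOA defense-phase S1 perturbation shrinks with iteration count", {
  # Eq-level property: amplitude envelope is C*(1 - t/T)*|y|
  C <- 0.01; T <- 100
  y <- 3
  amp <- function(t) C * (1 - t / T) * abs(y)
  expect_true(all(diff(vapply(c(0, 25, 50, 99), amp, numeric(1L))) < 0))
  # greedy acceptance never worsens any individual's fitness
  ds <- sel_data()
  st <- init_optimizer(ds$features, ds$labels, "zoa", small_ctl(),
                       rng_stream(6, "zoa"))
  fit_before <- st$fit
  zoa_iterate(st)
  expect_true(all(st$fit >= fit_before))
})

test_that("GSA masses normalize, flat populations get uniform mass, and H(n) matches its closed form", {
  ds <- sel_data()
  st <- init_optimizer(ds$features, ds$labels, "gsa", small_ctl(),
                       rng_stream(7, "gsa"))
  m <- neuroboost:::gsa_masses(st$fit)
  expect_equal(sum(m), 1)
  expect_equal(neuroboost:::gsa_masses(rep(50, 12)), rep(1 / 12, 12))
  ns <- 0:10
  expect_equal(gsa_gconst(ns, 200, 100, 20), 100 * exp(-20 * ns / 200))
})

test_that("a single GSA particle feels no force and drifts inertially", {
  ds <- sel_data()
  st <- init_optimizer(ds$features, ds$labels, "gsa", small_ctl(pop = 1L),
                       rng_stream(8, "gsa"))
  st$vel[] <- 0.5
  pos0 <- st$pos
  gsa_iterate(st, draws = list(force = matrix(0, 1, 1), inertia = 1))
  expect_equal(st$pos, neuroboost:::clamp(pos0 + 0.5, c(-5, 5)),
               ignore_attr = TRUE)
})

test_that("PSO is stationary at a converged fixed point and annihilates under zeroed rates", {
  ds <- sel_data()
  st <- init_optimizer(ds$features, ds$labels, "pso",
                       small_ctl(pop = 3L, theta = 0.5),
                       rng_stream(9, "pso"))
  # force particle 1 to sit at its pbest = gbest with zero velocity
  st$pos[1L, ] <- st$best$position
  st$pbest_pos[1L, ] <- st$best$position
  st$vel[1L, ] <- 0
  ones <- matrix(1, 3, st$p)
  pso_iterate(st, draws = list(c1 = ones, c2 = ones))
  expect_equal(st$pos[1L, ], st$best$position)
  # theta = 0, b1 = b2 = 0 zeroes the velocity in one step
  st2 <- init_optimizer(ds$features, ds$labels, "pso",
                        small_ctl(theta = 0, b1 = 0, b2 = 0),
                        rng_stream(10, "pso"))
  st2$vel[] <- 3
  pso_iterate(st2)
  expect_true(all(st2$vel == 0))
})

test_that("hybrid GSA-PSO reduces to its parents when one term is deleted", {
  ds <- sel_data()
  mk <- function(method, ctl) {
    init_optimizer(ds$features, ds$labels, method, ctl, rng_stream(11, "h"))
  }
  N <- 6L
  ones_nn <- matrix(0.5, N, N)
  # b1 = 0: velocity must equal the inertia+social PSO update with the
  # pbest term removed, computed here in closed form
  ctl <- small_ctl(pop = N, theta = 0.4, b1 = 0, b2 = 0.3)
  st <- mk("gsa_pso", ctl)
  ones <- matrix(1, N, st$p)
  pos0 <- st$pos; vel0 <- st$vel
  gbest <- matrix(st$best$position, N, st$p, byrow = TRUE)
  gsa_pso_iterate(st, draws = list(force = ones_nn, c1 = ones, c2 = ones))
  vel_expect <- 0.4 * vel0 + 0.3 * (gbest - pos0)
  expect_equal(st$vel, vel_expect, ignore_attr = TRUE)
  # b2 = 0: velocity must equal inertia + b1*accel, i.e. GSA kinematics
  ctl2 <- small_ctl(pop = N, theta = 0.4, b1 = 0.3, b2 = 0)
  st2 <- mk("gsa_pso", ctl2)
  pos0 <- st2$pos; vel0 <- st2$vel
  accel <- neuroboost:::gsa_acceleration(st2, draws = list(force = ones_nn))
  gsa_pso_iterate(st2, draws = list(force = ones_nn, c1 = ones, c2 = ones))
  expect_equal(st2$vel, 0.4 * vel0 + 0.3 * accel, ignore_attr = TRUE)
})

test_that("with T = 0 every selector returns the best initial candidate", {
  ds <- sel_data()
  for (m in c("cso", "rso", "cso_rso", "zoa", "gsa", "pso", "gsa_pso")) {
    fs <- select_features(ds$features, ds$labels, m, small_ctl(T = 0L),
                          seed = 12)
    st <- init_optimizer(ds$features, ds$labels, m, small_ctl(T = 0L),
                         rng_stream(12, paste0("select/", m)))
    expect_equal(fs$fitness, max(st$fit))
    expect_equal(fs$mask, st$mask[which.max(st$fit), ], ignore_attr = TRUE)
    expect_length(fs$trace, 1L)
  }
})

test_that("selector runs are deterministic and their traces are monotone within budget", {
  ds <- sel_data()
  per_iter <- c(cso = 2L, rso = 1L, cso_rso = 2L, zoa = 2L, gsa = 1L,
                pso = 1L, gsa_pso = 1L)
  for (m in names(per_iter)) {
    a <- select_features(ds$features, ds$labels, m, small_ctl(), seed = 13)
    b <- select_features(ds$features, ds$labels, m, small_ctl(), seed = 13)
    expect_identical(a$mask, b$mask)
    expect_identical(a$trace, b$trace)
    expect_true(all(diff(a$trace) >= 0))
    expect_true(all(rowSums(matrix(a$mask, 1L)) >= 1))
    budget <- 12L * (per_iter[[m]] * 8L + 1L) + a$repairs
    expect_lte(a$evals, budget)
    expect_length(a$trace, 9L)
  }
})

test_that("the pass-through selector keeps every feature", {
  ds <- sel_data()
  fs <- select_features(ds$features, ds$labels, "none")
  expect_equal(fs$indices, 1:10)
  expect_error(select_features(ds$features, ds$labels, "nope"),
               "unknown selector")
})

test_that("continuous PSO kinematics minimize the 5-D sphere function", {
  # pure continuous check of the kinematic core (no binarization): run the
  # same velocity/position rules on f(x) = sum(x^2)
  sphere_pso <- function(seed, pop = 100L, T = 200L, theta = 0.5,
                         b1 = 0.2, b2 = 0.4) {
    s <- rng_stream(seed, "sphere")
    d <- 5L
    pos <- matrix(stream_runif(s, pop * d, -5, 5), pop, d)
    vel <- matrix(0, pop, d)
    f <- rowSums(pos^2)
    pb <- pos; pbf <- f
    gb <- pos[which.min(f), ]; gbf <- min(f)
    for (t in seq_len(T)) {
      c1 <- matrix(stream_runif(s, pop * d), pop, d)
      c2 <- matrix(stream_runif(s, pop * d), pop, d)
      vel <- theta * vel + b1 * c1 * (pb - pos) +
        b2 * c2 * (matrix(gb, pop, d, byrow = TRUE) - pos)
      pos <- pos + vel
      f <- rowSums(pos^2)
      imp <- f < pbf
      pb[imp, ] <- pos[imp, , drop = FALSE]; pbf[imp] <- f[imp]
      if (min(f) < gbf) { gbf <- min(f); gb <- pos[which.min(f), ] }
    }
    gbf
  }
  vals <- vapply(1:5, sphere_pso, numeric(1L))
  expect_gte(sum(vals < 1e-2), 4L)
})
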