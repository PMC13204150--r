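#' Deterministic per-stage random streams
#'
#' Every stochastic stage of the pipeline (data generation, optimizer runs,
#' random network weights, fold shuffling) draws from its own stream derived
#' from a master seed and a stage tag, so a full run is bit-reproducible and
#' individual stages can be replayed in isolation.
#'
#' @param master_seed non-negative integer master seed.
#' @param tag character stage tag, e.g. `"cso"`, `"folds/r1"`.
#' @return An object of class `rng_stream` with its own Mersenne-Twister
#'   state, advanced only by draws made through [stream_runif()] and friends.
#' @examples
#' s <- rng_stream(7, "cso")
#' stream_runif(s, 3)
#' @export
rng_stream <- function(master_seed, tag) {
  if (!is.numeric(master_seed) || length(master_seed) != 1L ||
      is.na(master_seed) || master_seed < 0 || master_seed != floor(master_seed)) {
    stop("`master_seed` must be a single non-negative integer", call. = FALSE)
  }
  stopifnot(is.character(tag), length(tag) == 1L)
  sub <- derive_seed(master_seed, tag)
  env <- new.env(parent = emptyenv())
  env$tag <- tag
  env$seed <- sub
  env$state <- with_preserved_rng({
    set.seed(sub, kind = "Mersenne-Twister")
    get(".Random.seed", envir = globalenv())
  })
  class(env) <- "rng_stream"
  env
}

# 32-bit FNV-1a style hash of the tag folded with the master seed; kept
# below 2^31 - 1 so it is a valid R seed.
derive_seed <- function(master_seed, tag) {
  h <- 2166136261
  for (ch in utf8ToInt(tag)) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((h + (master_seed %% 2147483647) * 2654435761) %% 2147483647)
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

stream_eval <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  with_preserved_rng({
    assign(".Random.seed", stream$state, envir = globalenv())
    out <- expr
    stream$state <- get(".Random.seed", envir = globalenv())
    out
  })
}

#' @rdname rng_stream
#' @param stream an `rng_stream`.
#' @param n number of draws.
#' @param min,max uniform bounds.
#' @export
stream_runif <- function(stream, n, min = 0, max = 1) {
  stream_eval(stream, stats::runif(n, min, max))
}

#' @rdname rng_stream
#' @param sd standard deviation of normal draws.
#' @export
stream_rnorm <- function(stream, n, sd = 1) {
  stream_eval(stream, stats::rnorm(n, 0, sd))
}

#' @rdname rng_stream
#' @param x vector (or upper bound) to sample from, as in [sample()].
#' @param size sample size; defaults to the full permutation.
#' @param replace sample with replacement?
#' @param prob optional probability weights.
#' @export
stream_sample <- function(stream, x, size = NULL, replace = FALSE, prob = NULL) {
  if (is.null(size)) {
    size <- if (length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1) x
            else length(x)
  }
  stream_eval(stream, sample(x, size, replace = replace, prob = prob))
}

#' @rdname rng_stream
#' @export
substream <- function(stream, tag) {
  rng_stream(stream$seed, tag)
}

#' @export
print.rng_stream <- function(x, ...) {
  cat("<rng_stream tag=", x$tag, " seed=", x$seed, ">\n", sep = "")
  invisible(x)
}
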