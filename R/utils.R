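# Internal helpers: classed errors, seeded evaluation, sub-stream derivation.

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("ev_param_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("ev_input_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("ev_format_error", "error")))
}

stop_train <- function(...) {
  stop(errorCondition(paste0(...), class = c("ev_train_error", "error")))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
# A NULL seed evaluates in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_param("seed must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Independent sub-streams per purpose, derived from one base seed.
# Keeps results reproducible while decoupling e.g. splitting from training.
SUBSTREAMS <- c(split = 0L, init = 1L, train = 2L, eval = 3L, gen = 4L,
                pool = 5L, compose = 6L)

substream <- function(seed, purpose) {
  p <- SUBSTREAMS[[purpose]]
  (abs(as.integer(seed)) %% 268435456L) * 8L + p
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Population standard deviation (denominator n), used for RMS contrast.
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
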