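# Internal helpers: seeded RNG streams, argument checks.

# Named RNG streams derived from one user seed, so that e.g. bag sampling and
# parameter init are decoupled.  Offsets keep the derived seed < 2^31.
.stream_offsets <- c(
  slide = 101L, noise = 211L, bags = 307L, init = 401L,
  order = 503L, folds = 601L, misc = 701L
)

derive_seed <- function(seed, stream) {
  stopifnot(stream %in% names(.stream_offsets))
  as.integer((as.numeric(seed) * 7919 + .stream_offsets[[stream]]) %% 2147483647)
}

# Evaluate expr with a temporary RNG state seeded from (seed, stream).
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  expr
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

stop_degenerate <- function(msg) {
  stop(structure(
    class = c("lcmil_degenerate_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_config <- function(msg) {
  stop(structure(
    class = c("lcmil_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logistic <- function(x) 1 / (1 + exp(-x))
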