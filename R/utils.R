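#' @keywords internal
"_PACKAGE"

# logit / inverse-logit on methylation fractions
logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' Derive a stream seed from a master seed
#'
#' All randomness in the package is derived from a single master seed via
#' named streams, so that adding a stage never perturbs the draws of another.
#' The derived value is always a valid 32-bit integer seed.
#'
#' @param seed Master integer seed.
#' @param stream Character stream label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stream) == 1L)
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# run expr with a local RNG state seeded from (seed, stream); restores
# the caller's RNG so generators behave as pure functions of their inputs
with_stream_seed <- function(seed, stream, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(derive_seed(seed, stream))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
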