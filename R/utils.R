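#' @useDynLib topoforecast, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All package randomness funnels through
# this so a single run seed fans out reproducibly.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic 31-bit substream seed from a base seed and a stage
# name, so independent stages never share a stream.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 48271 + h * 2654435) %% 2147483647)
}

sigmoid <- function(x) {
  y <- stats::plogis(x)   # C implementation, saturation-safe
  if (is.matrix(x)) dim(y) <- dim(x)
  y
}

clamp01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# Mean binary cross-entropy with soft targets in [0, 1].
bce_loss <- function(p, y) {
  p <- clamp01(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
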