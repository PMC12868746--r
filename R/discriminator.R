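#' Discriminator state: two fully connected layers with sigmoid output
#'
#' The discriminator scores a (predicted or real) persistence image: the
#' flattened image is passed through two affine layers, each of the form
#' \eqn{Y = Sigmoid(W V + b)}, ending in a scalar probability in (0, 1)
#' that the image is real.
#'
#' @param resolution image side `R` (input size `R^2`).
#' @param hidden width of the first layer.
#' @param seed integer seed for the initialization.
#' @return a `discriminator_state`.
#' @export
discriminator_state <- function(resolution, hidden = 16L, seed = 1L) {
  R <- as.integer(resolution)
  N <- R * R
  h <- as.integer(hidden)
  with_seed(substream_seed(seed, "disc"), {
    s1 <- sqrt(6 / (N + h))
    s2 <- sqrt(6 / (h + 1))
    structure(list(
      resolution = R, n_pixels = N, hidden = h,
      params = list(W1 = matrix(stats::runif(N * h, -s1, s1), N, h),
                    b1 = numeric(h),
                    W2 = matrix(stats::runif(h, -s2, s2), h, 1L),
                    b2 = 0)
    ), class = "discriminator_state")
  })
}

# Batched forward: V is B x N (one flattened image per row).
discriminator_forward_batch <- function(disc, V, keep_cache = FALSE) {
  stopifnot(ncol(V) == disc$n_pixels)
  p <- disc$params
  A1 <- sigmoid(sweep(V %*% p$W1, 2L, p$b1, `+`))
  y <- as.vector(sigmoid(A1 %*% p$W2 + p$b2))
  list(y = y, cache = if (keep_cache) list(V = V, A1 = A1, y = y) else NULL)
}

# Backward from dlogit2 (gradient at the output pre-sigmoid logit, length B).
# Returns parameter gradients and dV (B x N), the gradient w.r.t. the input
# images (used to train the generator through the discriminator).
discriminator_backward <- function(disc, cache, dlogit2) {
  p <- disc$params
  dlogit2 <- matrix(dlogit2, ncol = 1L)
  gW2 <- crossprod(cache$A1, dlogit2)
  gb2 <- sum(dlogit2)
  dA1 <- dlogit2 %*% t(p$W2)
  dz1 <- dA1 * cache$A1 * (1 - cache$A1)
  gW1 <- crossprod(cache$V, dz1)
  gb1 <- colSums(dz1)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
       dV = dz1 %*% t(p$W1))
}

#' Discriminator probability for one persistence image
#'
#' @param disc a `discriminator_state`.
#' @param pi `R x R` image (or a flattened length-`R^2` vector).
#' @return scalar probability in (0, 1).
#' @export
discriminator_forward <- function(disc, pi) {
  stopifnot(inherits(disc, "discriminator_state"))
  v <- if (is.matrix(pi) && !identical(dim(pi), c(1L, disc$n_pixels))) {
    if (!all(dim(pi) == disc$resolution)) {
      stop("image is ", paste(dim(pi), collapse = " x "),
           " but the discriminator expects ", disc$resolution, " x ",
           disc$resolution)
    }
    flatten_pi(pi)
  } else as.vector(pi)
  if (length(v) != disc$n_pixels) stop("flattened image has wrong length")
  discriminator_forward_batch(disc, matrix(v, nrow = 1L))$y
}
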