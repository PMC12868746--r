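#' Generator state: two GAT layers, an LSTM over pixels, a sigmoid head
#'
#' The full generator maps a persistence image to the predicted next-window
#' image: pixel-grid graph -> 8-head GAT (width `gat_hidden`) -> single-head
#' GAT back to one feature per node -> flatten to an `R^2 x 1` sequence ->
#' LSTM with scalar inputs and hidden size `lstm_hidden` (default 5) -> the
#' last hidden state through an affine map to `R^2` logits -> sigmoid ->
#' reshape to `R x R`. Ablation variants: `"gat_only"` replaces the
#' LSTM/affine tail with a shared per-node affine + sigmoid; `"lstm_only"`
#' feeds the flattened input image straight into the LSTM.
#'
#' @param resolution image side `R`.
#' @param gat_heads heads of the first attention layer (default 8).
#' @param gat_hidden per-head output width of the first layer.
#' @param lstm_hidden LSTM hidden-state dimension (default 5).
#' @param neighborhood grid neighbourhood, 4 or 8.
#' @param dropout dropout rate on first-layer attention coefficients and
#'   input node features during training (default 0.6).
#' @param variant `"full"`, `"gat_only"` or `"lstm_only"`.
#' @param activation GAT output nonlinearity.
#' @param seed integer seed for the parameter initialization.
#' @return a `generator_state`.
#' @export
generator_state <- function(resolution, gat_heads = 8L, gat_hidden = 8L,
                            lstm_hidden = 5L, neighborhood = 8L,
                            dropout = 0.6,
                            variant = c("full", "gat_only", "lstm_only"),
                            activation = "elu", seed = 1L) {
  variant <- match.arg(variant)
  R <- as.integer(resolution)
  N <- R * R
  H <- as.integer(lstm_hidden)
  gat1 <- gat_layer_params(gat_heads, 1L, gat_hidden,
                           activation = activation,
                           seed = substream_seed(seed, "gat1"))
  gat2 <- gat_layer_params(1L, gat_hidden, 1L, activation = activation,
                           seed = substream_seed(seed, "gat2"))
  lstm <- with_seed(substream_seed(seed, "lstm"), {
    s <- sqrt(6 / (1 + H))
    b <- numeric(4L * H)
    b[seq_len(H) + H] <- 1          # forget-gate bias starts open
    list(Wx = stats::runif(4L * H, -s, s),
         Wh = matrix(stats::runif(H * 4L * H, -s, s), H, 4L * H),
         b = b)
  })
  fc <- with_seed(substream_seed(seed, "fc"), {
    s <- sqrt(6 / (H + 1))
    list(W = matrix(stats::runif(H * N, -s, s), H, N), b = numeric(N))
  })
  structure(list(
    resolution = R, n_pixels = N, lstm_hidden = H,
    neighborhood = as.integer(neighborhood), dropout = dropout,
    variant = variant,
    params = list(gat1 = gat1, gat2 = gat2, lstm = lstm, fc = fc,
                  head = list(scale = 1, bias = 0))
  ), class = "generator_state")
}

#' @export
print.generator_state <- function(x, ...) {
  cat(sprintf("<generator_state> R = %d (%d pixels), variant = %s, %d parameters\n",
              x$resolution, x$n_pixels, x$variant, count_params(x)))
  invisible(x)
}

#' Number of learnable parameters of a generator variant
#'
#' Counts only the parameters the variant actually uses (the GAT stack for
#' `gat_only`, the LSTM tail for `lstm_only`, both for `full`).
#'
#' @param gen a `generator_state`.
#' @return integer count.
#' @export
count_params <- function(gen) {
  p <- gen$params
  n_gat <- sum(lengths(p$gat1$W)) + sum(lengths(p$gat1$a_dst)) +
    sum(lengths(p$gat1$a_src)) + sum(lengths(p$gat2$W)) +
    sum(lengths(p$gat2$a_dst)) + sum(lengths(p$gat2$a_src))
  n_lstm <- length(p$lstm$Wx) + length(p$lstm$Wh) + length(p$lstm$b)
  n_fc <- length(p$fc$W) + length(p$fc$b)
  switch(gen$variant,
         full = n_gat + n_lstm + n_fc,
         gat_only = n_gat + 2L,
         lstm_only = n_lstm + n_fc)
}

# ---- batched GAT forward (generator-internal fast path) -------------------
#
# X: N x B matrix of input node features (one column per sample, f_in = 1).
# Returns list(H2 = N x B output of the second layer, cache).

gat_stack_forward <- function(gen, graph, X, training = FALSE) {
  p <- gen$params
  dst <- graph$dst; src <- graph$src
  n <- graph$n_nodes
  slope1 <- p$gat1$leaky_slope
  drop <- if (training) gen$dropout else 0

  Xd <- X
  mask_x <- NULL
  if (drop > 0) {
    mask_x <- matrix((stats::runif(length(X)) >= drop) / (1 - drop),
                     nrow(X), ncol(X))
    Xd <- X * mask_x
  }
  K <- p$gat1$K
  F1 <- p$gat1$f_out
  B <- ncol(X)
  pre1 <- matrix(0, n * B, F1)
  heads <- vector("list", K)
  for (k in seq_len(K)) {
    w <- as.vector(p$gat1$W[[k]])
    c_d <- sum(w * p$gat1$a_dst[[k]])
    c_s <- sum(w * p$gat1$a_src[[k]])
    e <- c_d * Xd[dst, , drop = FALSE] + c_s * Xd[src, , drop = FALSE]
    l <- leaky_relu(e, slope1)
    dfac <- (slope1 + (1 - slope1) * (e > 0)) * ((l > -25) & (l < 25))
    alpha <- edge_softmax(l, dst, n)
    m_a <- NULL
    alpha_used <- alpha
    if (drop > 0) {
      m_a <- matrix((stats::runif(length(alpha)) >= drop) / (1 - drop),
                    nrow(alpha), ncol(alpha))
      alpha_used <- alpha * m_a
    }
    S <- rowsum(alpha_used * Xd[src, , drop = FALSE], dst)
    pre1 <- pre1 + as.vector(S) %o% (w / K)
    heads[[k]] <- list(alpha = alpha, alpha_used = alpha_used, m_a = m_a,
                       dfac = dfac, S = S)
  }
  H1 <- gat_act(pre1, p$gat1$activation)        # (N*B) x F1

  W2 <- as.vector(p$gat2$W[[1]])
  a_d2 <- p$gat2$a_dst[[1]]
  a_s2 <- p$gat2$a_src[[1]]
  slope2 <- p$gat2$leaky_slope
  WH2 <- matrix(H1 %*% W2, n, B)
  e2 <- a_d2 * WH2[dst, , drop = FALSE] + a_s2 * WH2[src, , drop = FALSE]
  l2 <- leaky_relu(e2, slope2)
  dfac2 <- (slope2 + (1 - slope2) * (e2 > 0)) * ((l2 > -25) & (l2 < 25))
  alpha2 <- edge_softmax(l2, dst, n)
  pre2 <- rowsum(alpha2 * WH2[src, , drop = FALSE], dst)
  H2 <- gat_act(pre2, p$gat2$activation)

  list(H2 = H2,
       cache = list(Xd = Xd, mask_x = mask_x, heads = heads, pre1 = pre1,
                    H1 = H1, WH2 = WH2, alpha2 = alpha2, dfac2 = dfac2,
                    pre2 = pre2, B = B, n = n))
}

# Backward through both GAT layers. dH2: N x B gradient at the stack output.
# Returns parameter gradients (input gradients are not needed: the stack
# input is data).
gat_stack_backward <- function(gen, graph, cache, dH2) {
  p <- gen$params
  dst <- graph$dst; src <- graph$src
  n <- cache$n; B <- cache$B
  W2 <- as.vector(p$gat2$W[[1]])
  a_d2 <- p$gat2$a_dst[[1]]
  a_s2 <- p$gat2$a_src[[1]]

  dpre2 <- dH2 * gat_act_grad(cache$pre2, p$gat2$activation)
  alpha2 <- cache$alpha2
  WH2 <- cache$WH2
  dalpha2 <- dpre2[dst, , drop = FALSE] * WH2[src, , drop = FALSE]
  dWH2 <- rowsum(alpha2 * dpre2[dst, , drop = FALSE], src)
  gsum2 <- rowsum(dalpha2 * alpha2, dst)
  dl2 <- alpha2 * (dalpha2 - gsum2[dst, , drop = FALSE])
  de2 <- dl2 * cache$dfac2
  da_d2 <- sum(de2 * WH2[dst, , drop = FALSE])
  da_s2 <- sum(de2 * WH2[src, , drop = FALSE])
  dWH2 <- dWH2 + a_d2 * rowsum(de2, dst) + a_s2 * rowsum(de2, src)
  dW2 <- as.vector(crossprod(cache$H1, as.vector(dWH2)))
  dH1 <- as.vector(dWH2) %o% W2

  dpre1 <- dH1 * gat_act_grad(cache$pre1, p$gat1$activation)
  K <- p$gat1$K
  Xd <- cache$Xd
  g1 <- list(W = vector("list", K), a_dst = vector("list", K),
             a_src = vector("list", K))
  for (k in seq_len(K)) {
    hc <- cache$heads[[k]]
    w <- as.vector(p$gat1$W[[k]])
    dS <- matrix(dpre1 %*% (w / K), n, B)
    dw <- as.vector(crossprod(dpre1, as.vector(hc$S))) / K
    dalpha <- dS[dst, , drop = FALSE] * Xd[src, , drop = FALSE]
    if (!is.null(hc$m_a)) dalpha <- dalpha * hc$m_a
    gs <- rowsum(dalpha * hc$alpha, dst)
    dl <- hc$alpha * (dalpha - gs[dst, , drop = FALSE])
    de <- dl * hc$dfac
    dc_d <- sum(de * Xd[dst, , drop = FALSE])
    dc_s <- sum(de * Xd[src, , drop = FALSE])
    dw <- dw + dc_d * p$gat1$a_dst[[k]] + dc_s * p$gat1$a_src[[k]]
    g1$W[[k]] <- matrix(dw, 1L, length(w))
    g1$a_dst[[k]] <- dc_d * w
    g1$a_src[[k]] <- dc_s * w
  }
  list(gat1 = g1,
       gat2 = list(W = list(matrix(dW2, ncol = 1L)),
                   a_dst = list(da_d2), a_src = list(da_s2)))
}

# ---- batched LSTM over the flattened pixel sequence -----------------------
#
# Z: N x B (step t reads row t, scalar input per sample). Hidden size H.
# Gate order along the 4H axis: input, forget, output, candidate.

lstm_forward <- function(lstm, Z, H) {
  n <- nrow(Z); B <- ncol(Z)
  # per-step caches stored as row blocks of (n*B) x H matrices; the block
  # for step t is rows (t-1)*B + 1 .. t*B
  i_ <- f_ <- o_ <- g_ <- Ct <- Tc <- Hprev <- matrix(0, n * B, H)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Gx_all <- as.vector(t(Z)) %o% lstm$Wx       # (n*B) x 4H, input products
  Gx_all <- sweep(Gx_all, 2L, lstm$b, `+`)
  ii <- seq_len(H); fi <- H + ii; oi <- 2L * H + ii; gi_ <- 3L * H + ii
  for (t in seq_len(n)) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    Hprev[rows, ] <- h
    G <- Gx_all[rows, , drop = FALSE] + h %*% lstm$Wh
    gi <- sigmoid(G[, ii, drop = FALSE])
    gf <- sigmoid(G[, fi, drop = FALSE])
    go <- sigmoid(G[, oi, drop = FALSE])
    gg <- tanh(G[, gi_, drop = FALSE])
    cc <- gf * cc + gi * gg
    tc <- tanh(cc)
    h <- go * tc
    i_[rows, ] <- gi; f_[rows, ] <- gf; o_[rows, ] <- go; g_[rows, ] <- gg
    Ct[rows, ] <- cc; Tc[rows, ] <- tc
  }
  list(h_last = h,
       cache = list(Z = Z, i = i_, f = f_, o = o_, g = g_, C = Ct, Tc = Tc,
                    Hprev = Hprev, H = H, n = n, B = B))
}

# dh_last: B x H gradient at the final hidden state. Returns parameter
# gradients and dZ (N x B), the gradient w.r.t. the input sequence.
lstm_backward <- function(lstm, cache, dh_last) {
  n <- cache$n; B <- cache$B; H <- cache$H
  dWh <- matrix(0, H, 4L * H)
  dG_all <- matrix(0, n * B, 4L * H)
  dh <- dh_last
  dc <- matrix(0, B, H)
  tWh <- t(lstm$Wh)
  zeroBH <- matrix(0, B, H)
  for (t in rev(seq_len(n))) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    gi <- cache$i[rows, , drop = FALSE]
    gf <- cache$f[rows, , drop = FALSE]
    go <- cache$o[rows, , drop = FALSE]
    gg <- cache$g[rows, , drop = FALSE]
    tc <- cache$Tc[rows, , drop = FALSE]
    cprev <- if (t > 1L) cache$C[rows - B, , drop = FALSE] else zeroBH
    do_ <- dh * tc
    dc <- dc + dh * go * (1 - tc^2)
    dG <- cbind((dc * gg) * gi * (1 - gi), (dc * cprev) * gf * (1 - gf),
                do_ * go * (1 - go), (dc * gi) * (1 - gg^2))
    dG_all[rows, ] <- dG
    dWh <- dWh + crossprod(cache$Hprev[rows, , drop = FALSE], dG)
    dh <- dG %*% tWh
    dc <- dc * gf
  }
  dWx <- as.vector(crossprod(dG_all, as.vector(t(cache$Z))))
  db <- colSums(dG_all)
  dZ <- matrix(dG_all %*% lstm$Wx, B, n)   # rows within block = samples
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dZ = t(dZ))
}

# ---- generator forward/backward -------------------------------------------

#' Batched generator forward pass
#'
#' Internal fast path used by training: takes a matrix of flattened
#' (row-major) input images, one column per sample, and returns the
#' predicted images as rows of a `B x R^2` matrix in `[0, 1]`.
#'
#' @param gen a `generator_state`.
#' @param X `N x B` matrix of flattened input images.
#' @param training enable dropout (uses the current RNG stream).
#' @param keep_cache retain intermediates for [generator_backward()].
#' @return list with `P` (`B x N` predictions) and `cache`.
#' @keywords internal
generator_forward_batch <- function(gen, X, training = FALSE,
                                    keep_cache = FALSE) {
  stopifnot(nrow(X) == gen$n_pixels)
  graph <- grid_graph(gen$resolution, gen$resolution, gen$neighborhood)
  p <- gen$params
  cache <- list(variant = gen$variant)

  Z <- X
  if (gen$variant != "lstm_only") {
    gs <- gat_stack_forward(gen, graph, X, training = training)
    Z <- gs$H2
    cache$gat <- gs$cache
  }
  if (gen$variant == "gat_only") {
    logits <- p$head$scale * Z + p$head$bias
    P <- t(sigmoid(logits))
    cache$Z <- Z
  } else {
    lf <- lstm_forward(p$lstm, Z, gen$lstm_hidden)
    logits <- lf$h_last %*% p$fc$W +
      matrix(p$fc$b, ncol(X), gen$n_pixels, byrow = TRUE)
    P <- sigmoid(logits)
    cache$lstm <- lf$cache
    cache$h_last <- lf$h_last
  }
  cache$P <- P
  list(P = P, cache = if (keep_cache) cache else NULL)
}

#' Batched generator backward pass
#'
#' Backpropagates a gradient w.r.t. the pre-sigmoid output logits through
#' the generator and returns parameter gradients in the shape of
#' `gen$params`.
#'
#' @param gen a `generator_state`.
#' @param cache cache from [generator_forward_batch()].
#' @param dlogit `B x N` gradient of the loss w.r.t. the output logits.
#' @return nested list of gradients.
#' @keywords internal
generator_backward <- function(gen, cache, dlogit) {
  p <- gen$params
  graph <- grid_graph(gen$resolution, gen$resolution, gen$neighborhood)
  grads <- list()
  if (gen$variant == "gat_only") {
    dZ <- t(dlogit) * p$head$scale
    grads$head <- list(scale = sum(t(dlogit) * cache$Z),
                       bias = sum(dlogit))
    grads <- c(grads, gat_stack_backward(gen, graph, cache$gat, dZ))
    return(grads)
  }
  grads$fc <- list(W = crossprod(cache$h_last, dlogit),
                   b = colSums(dlogit))
  dh_last <- dlogit %*% t(p$fc$W)
  lb <- lstm_backward(p$lstm, cache$lstm, dh_last)
  grads$lstm <- lb$grads
  if (gen$variant == "full") {
    grads <- c(grads, gat_stack_backward(gen, graph, cache$gat, lb$dZ))
  }
  grads
}

#' Predict the next-window persistence image
#'
#' Runs the generator pipeline on one image: grid graph -> GAT layers ->
#' flatten -> LSTM over the `R^2` pixel sequence -> affine + sigmoid ->
#' reshape. All outputs lie in `[0, 1]`. With `training = FALSE` the pass is
#' deterministic (no dropout).
#'
#' @param gen a `generator_state`.
#' @param pi input `persistence_image` (matrix `R x R`).
#' @param training enable dropout.
#' @return predicted `persistence_image` with attribute `flow` recording the
#'   internal shapes (post-GAT grid, LSTM sequence length).
#' @export
generator_forward <- function(gen, pi, training = FALSE) {
  stopifnot(inherits(gen, "generator_state"), is.matrix(pi))
  if (!all(dim(pi) == gen$resolution)) {
    stop("image is ", paste(dim(pi), collapse = " x "),
         " but the generator expects ", gen$resolution, " x ",
         gen$resolution)
  }
  X <- matrix(flatten_pi(pi), ncol = 1L)
  out <- generator_forward_batch(gen, X, training = training)
  img <- unflatten_pi(as.vector(out$P), c(gen$resolution, gen$resolution))
  attr(img, "flow") <- list(
    post_gat_grid = c(gen$resolution, gen$resolution),
    lstm_input_length = if (gen$variant == "gat_only") NA_integer_ else
      gen$n_pixels)
  img
}
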