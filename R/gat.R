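#' Parameters of one graph-attention layer
#'
#' A layer holds, per head \eqn{k}: a weight map \eqn{W^k} (`f_in x f_out`),
#' and an attention vector over the concatenated transformed pair, split
#' here into its destination and source halves (`a_dst`, `a_src`, each of
#' length `f_out`). The unnormalized score for edge \eqn{(i, j)} is
#' \eqn{e_{ij} = a_{dst} \cdot W h_i + a_{src} \cdot W h_j}; scores are
#' passed through a LeakyReLU and softmax-normalized over each node's
#' neighbourhood. Head outputs are aggregated by averaging
#' (\eqn{h'_i = \sigma(\frac{1}{K}\sum_k \sum_{j \in N_i} a^k_{ij} W^k h_j)}).
#'
#' @param n_heads number of attention heads K.
#' @param f_in,f_out input/output feature widths.
#' @param leaky_slope negative slope of the LeakyReLU on raw scores.
#' @param activation output nonlinearity: `"elu"`, `"sigmoid"` or
#'   `"linear"`.
#' @param init `"glorot"` for uniform Glorot initialization, `"zero"`, or
#'   `"identity"` (requires `f_in == f_out`).
#' @param seed integer seed for the initialization.
#' @return a `gat_layer` list.
#' @export
gat_layer_params <- function(n_heads, f_in, f_out, leaky_slope = 0.2,
                             activation = c("elu", "sigmoid", "linear"),
                             init = c("glorot", "zero", "identity"),
                             seed = 1L) {
  activation <- match.arg(activation)
  init <- match.arg(init)
  make_w <- function() {
    switch(init,
           glorot = {
             s <- sqrt(6 / (f_in + f_out))
             matrix(stats::runif(f_in * f_out, -s, s), f_in, f_out)
           },
           zero = matrix(0, f_in, f_out),
           identity = {
             stopifnot(f_in == f_out)
             diag(f_in)
           })
  }
  make_a <- function() {
    if (init == "glorot") {
      s <- sqrt(6 / (f_out + 1))
      stats::runif(f_out, -s, s)
    } else numeric(f_out)
  }
  with_seed(seed, {
    structure(list(
      K = as.integer(n_heads), f_in = as.integer(f_in),
      f_out = as.integer(f_out),
      W = lapply(seq_len(n_heads), function(k) make_w()),
      a_dst = lapply(seq_len(n_heads), function(k) make_a()),
      a_src = lapply(seq_len(n_heads), function(k) make_a()),
      leaky_slope = leaky_slope, activation = activation
    ), class = "gat_layer")
  })
}

leaky_relu <- function(x, slope) x * (slope + (1 - slope) * (x > 0))

gat_act <- function(x, activation) {
  switch(activation,
         elu = {
           y <- x
           neg <- which(x < 0)
           y[neg] <- expm1(x[neg])
           y
         },
         sigmoid = sigmoid(x),
         linear = x)
}

gat_act_grad <- function(x, activation) {
  switch(activation,
         elu = {
           g <- (x >= 0) + 0
           neg <- which(x < 0)
           g[neg] <- exp(x[neg])
           g
         },
         sigmoid = { s <- sigmoid(x); s * (1 - s) },
         linear = array(1, dim(x) %||% length(x)))
}

# Numerically safe softmax over edge scores grouped by destination node:
# scores are clamped to +/- 25 before exponentiation. `dst` must cover
# 1..n_nodes (guaranteed by self-loops).
edge_softmax <- function(scores, dst, n_nodes) {
  sc <- pmin(pmax(scores, -25), 25)
  ex <- exp(sc)
  den <- rowsum(ex, dst)
  if (nrow(den) != n_nodes) stop("internal error: node without neighbours")
  ex / den[dst, , drop = FALSE]
}

#' Attention coefficients of one head on a graph
#'
#' Computes the raw scores \eqn{e_{ij}} and softmax-normalized coefficients
#' \eqn{a_{ij}} of head `k` for every directed edge of the graph. For each
#' node \eqn{i}, \eqn{\sum_{j \in N_i} a_{ij} = 1}.
#'
#' @param graph a `pi_graph` with `node_features` set.
#' @param layer a `gat_layer`.
#' @param head head index in `1..K`.
#' @return list with `e` (raw scores), `alpha` (normalized coefficients),
#'   `dst`, `src` (edge endpoints, `src[n] in N_(dst[n])`).
#' @export
attention_scores <- function(graph, layer, head = 1L) {
  stopifnot(inherits(graph, "pi_graph"), inherits(layer, "gat_layer"),
            head >= 1, head <= layer$K)
  H <- graph$node_features
  stopifnot(is.matrix(H), ncol(H) == layer$f_in)
  WH <- H %*% layer$W[[head]]
  e <- as.vector(WH %*% layer$a_dst[[head]])[graph$dst] +
    as.vector(WH %*% layer$a_src[[head]])[graph$src]
  l <- leaky_relu(e, layer$leaky_slope)
  alpha <- edge_softmax(matrix(l, ncol = 1L), graph$dst, graph$n_nodes)
  list(e = e, alpha = as.vector(alpha), dst = graph$dst, src = graph$src)
}

#' Forward pass of a graph-attention layer
#'
#' Updates the node features by K-head average aggregation:
#' \eqn{h'_i = \sigma(\frac{1}{K} \sum_{k=1}^K \sum_{j \in N_i} a^k_{ij} W^k h_j)}.
#' The grid shape (and hence image size) is unchanged.
#'
#' @param graph a `pi_graph` with `node_features` (`N x f_in`).
#' @param layer a `gat_layer`.
#' @param training apply dropout to attention coefficients?
#' @param dropout dropout rate used when `training = TRUE`.
#' @return the graph with `node_features` replaced by the `N x f_out`
#'   output.
#' @export
gat_forward <- function(graph, layer, training = FALSE, dropout = 0) {
  stopifnot(inherits(graph, "pi_graph"), inherits(layer, "gat_layer"))
  H <- graph$node_features
  if (ncol(H) != layer$f_in) {
    stop("feature-dimension mismatch: got ", ncol(H), ", layer expects ",
         layer$f_in)
  }
  pre <- matrix(0, graph$n_nodes, layer$f_out)
  for (k in seq_len(layer$K)) {
    WH <- H %*% layer$W[[k]]
    att <- attention_scores(graph, layer, k)
    alpha <- att$alpha
    if (training && dropout > 0) {
      mask <- stats::rbinom(length(alpha), 1L, 1 - dropout) / (1 - dropout)
      alpha <- alpha * mask
    }
    pre <- pre + rowsum(alpha * WH[graph$src, , drop = FALSE], graph$dst)
  }
  pre <- pre / layer$K
  dimnames(pre) <- NULL
  graph$node_features <- gat_act(pre, layer$activation)
  graph
}
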