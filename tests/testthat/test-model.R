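toy_graph <- function(features, dst, src) {
  structure(list(node_features = features, dst = dst, src = src,
                 grid_shape = c(nrow(features), 1L),
                 n_nodes = nrow(features), neighborhood = 8L),
            class = "pi_graph")
}

test_that("attention coefficients are softmax-normalized per node", {
  # isolated node: a self-loop is the whole neighbourhood
  g1 <- toy_graph(matrix(0.7, 1, 1), dst = 1L, src = 1L)
  layer <- gat_layer_params(1, 1, 4, seed = 3)
  att <- attention_scores(g1, layer, 1)
  expect_equal(att$alpha, 1)

  # two neighbours with identical features share the weight equally
  g2 <- toy_graph(matrix(c(0.2, 0.9, 0.9), 3, 1),
                  dst = c(1L, 1L, 2L, 3L), src = c(2L, 3L, 2L, 3L))
  att2 <- attention_scores(g2, layer, 1)
  expect_equal(att2$alpha[1:2], c(0.5, 0.5))

  # random graphs/parameters: per-node sums are 1 within 1e-6, both layers
  set.seed(11)
  for (i in 1:5) {
    pi_img <- matrix(runif(36), 6, 6)
    g <- pi_to_graph(pi_img, neighborhood = sample(c(4L, 8L), 1))
    l1 <- gat_layer_params(8, 1, 8, seed = i)
    for (k in c(1, 4, 8)) {
      a <- attention_scores(g, l1, k)
      sums <- rowsum(a$alpha, a$dst)
      expect_true(all(abs(sums - 1) < 1e-6))
    }
    g2 <- gat_forward(g, l1)
    l2 <- gat_layer_params(1, 8, 1, seed = i + 50)
    a2 <- attention_scores(g2, l2, 1)
    expect_true(all(abs(rowsum(a2$alpha, a2$dst) - 1) < 1e-6))
  }
})

test_that("a linear identity layer fixes an isolated node's feature", {
  g <- toy_graph(matrix(0.37, 1, 1), dst = 1L, src = 1L)
  layer <- gat_layer_params(1, 1, 1, activation = "linear",
                            init = "identity")
  out <- gat_forward(g, layer)
  expect_equal(out$node_features, matrix(0.37, 1, 1))
})

test_that("gat_forward matches a dense per-node oracle on a toy grid", {
  set.seed(5)
  pi_img <- matrix(runif(9), 3, 3)
  g <- pi_to_graph(pi_img, neighborhood = 8)
  layer <- gat_layer_params(3, 1, 4, seed = 9)
  got <- gat_forward(g, layer)$node_features
  want <- gat_dense_oracle(graph_adjacency(g), g$node_features, layer)
  expect_equal(got, want, tolerance = 1e-10, ignore_attr = TRUE)

  # second-layer shapes: 8 features in, 1 out, grid preserved
  l2 <- gat_layer_params(1, 4, 1, seed = 10)
  out2 <- gat_forward(gat_forward(g, layer), l2)
  expect_equal(dim(out2$node_features), c(9L, 1L))
  expect_equal(out2$grid_shape, g$grid_shape)

  expect_error(gat_forward(g, l2), "mismatch")
})

test_that("generator output is a [0,1] image of the input shape", {
  gen <- generator_state(6, seed = 2)
  pi_img <- matrix(runif(36), 6, 6)
  out <- generator_forward(gen, pi_img)
  expect_equal(dim(out), c(6L, 6L))
  expect_true(all(out >= 0 & out <= 1))

  # zeroed output head pins every pixel to sigmoid(0) = 0.5
  gen0 <- gen
  gen0$params$fc$W[] <- 0
  gen0$params$fc$b[] <- 0
  expect_true(all(generator_forward(gen0, pi_img) == 0.5))

  # inference is deterministic; dropout only acts in training mode
  expect_identical(generator_forward(gen, pi_img),
                   generator_forward(gen, pi_img))
  expect_error(generator_forward(gen, matrix(0, 4, 4)), "expects")
})

test_that("batched and single-image generator paths agree", {
  gen <- generator_state(5, seed = 8)
  imgs <- lapply(1:3, function(i) matrix(runif(25), 5, 5))
  X <- do.call(cbind, lapply(imgs, flatten_pi))
  P <- topoforecast:::generator_forward_batch(gen, X)$P
  for (i in 1:3) {
    expect_equal(as.vector(t(generator_forward(gen, imgs[[i]]))),
                 unname(P[i, ]), tolerance = 1e-12)
  }
})

test_that("ablation variants emit valid images and order by parameter count", {
  vs <- ablation_variants(5, seed = 4)
  pi_img <- matrix(runif(25), 5, 5)
  for (v in vs) {
    out <- generator_forward(v, pi_img)
    expect_equal(dim(out), c(5L, 5L))
    expect_true(all(out >= 0 & out <= 1))
  }
  expect_lt(count_params(vs$gat_only), count_params(vs$full))
  expect_lt(count_params(vs$lstm_only), count_params(vs$full))
})

test_that("discriminator is a two-layer sigmoid map with sane responses", {
  disc <- discriminator_state(4, seed = 6)
  img <- matrix(runif(16), 4, 4)
  y <- discriminator_forward(disc, img)
  expect_length(y, 1)
  expect_true(y > 0 && y < 1)

  d0 <- disc
  d0$params$W1[] <- 0; d0$params$b1[] <- 0
  d0$params$W2[] <- 0; d0$params$b2 <- 0
  expect_equal(discriminator_forward(d0, img), 0.5)

  # hand-computed value: all-ones first layer collapsed to one unit
  dh <- discriminator_state(2, hidden = 1, seed = 1)
  dh$params$W1 <- matrix(1, 4, 1); dh$params$b1 <- 0
  dh$params$W2 <- matrix(2, 1, 1); dh$params$b2 <- -0.5
  v <- c(0.1, 0.2, 0.3, 0.4)
  hand <- plogis(2 * plogis(sum(v)) - 0.5)
  expect_equal(discriminator_forward(dh, v), hand, tolerance = 1e-12)

  # strictly increasing final-layer logit => strictly increasing output
  logits <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(plogis(logits)) > 0))
  expect_error(discriminator_forward(disc, matrix(0, 3, 3)), "expects")
})

test_that("backpropagated gradients match finite differences (R = 4)", {
  tf <- asNamespace("topoforecast")
  R <- 4
  set.seed(7)
  X <- matrix(runif(R * R * 3), R * R, 3)
  Y <- t(matrix(runif(R * R * 3), R * R, 3))
  gen <- generator_state(R, seed = 3)
  lossfn <- function(g) {
    tf$bce_loss(tf$generator_forward_batch(g, X)$P, Y)
  }
  fw <- tf$generator_forward_batch(gen, X, keep_cache = TRUE)
  gr <- tf$generator_backward(gen, fw$cache,
                              (tf$clamp01(fw$P) - Y) / length(Y))
  eps <- 1e-6
  probes <- list(
    list(get = function(g) g$params$fc$W[2, 7],
         set = function(g, v) { g$params$fc$W[2, 7] <- v; g },
         an = gr$fc$W[2, 7]),
    list(get = function(g) g$params$lstm$Wh[3, 12],
         set = function(g, v) { g$params$lstm$Wh[3, 12] <- v; g },
         an = gr$lstm$Wh[3, 12]),
    list(get = function(g) g$params$gat1$W[[2]][1, 3],
         set = function(g, v) { g$params$gat1$W[[2]][1, 3] <- v; g },
         an = gr$gat1$W[[2]][1, 3]),
    list(get = function(g) g$params$gat2$a_src[[1]],
         set = function(g, v) { g$params$gat2$a_src[[1]] <- v; g },
         an = gr$gat2$a_src[[1]])
  )
  for (pr in probes) {
    fd <- (lossfn(pr$set(gen, pr$get(gen) + eps)) -
             lossfn(pr$set(gen, pr$get(gen) - eps))) / (2 * eps)
    expect_lt(rel_err(fd, pr$an), 1e-4)
  }
})
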