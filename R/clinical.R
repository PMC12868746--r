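# Convolutional image-quality regressor: two conv(3x3)+max-pool blocks, a
# hidden dense layer, and a scalar regression head, trained with Adam on
# mean squared error. The per-sample outputs of the trained model are the
# "image quality coefficients" that are correlated with clinical scores.

conv_forward <- function(X, W, b) {
  d <- dim(X)                       # (B, H, W, Cin)
  B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  Ho <- H - 2L; Wo <- Wd - 2L
  Cout <- dim(W)[4]
  acc <- matrix(0, B * Ho * Wo, Cout)
  for (di in 0:2) {
    for (dj in 0:2) {
      Xs <- X[, di + seq_len(Ho), dj + seq_len(Wo), , drop = FALSE]
      dim(Xs) <- c(B * Ho * Wo, Cin)
      acc <- acc + Xs %*% matrix(W[di + 1L, dj + 1L, , ], Cin, Cout)
    }
  }
  acc <- sweep(acc, 2L, b, `+`)
  pre <- array(acc, c(B, Ho, Wo, Cout))
  list(out = pmax(pre, 0), pre = pre, X = X)
}

conv_backward <- function(cache, W, dOut, need_dX = TRUE) {
  X <- cache$X
  d <- dim(X)
  B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  Ho <- H - 2L; Wo <- Wd - 2L
  Cout <- dim(W)[4]
  dPre <- dOut * (cache$pre > 0)
  dPm <- dPre; dim(dPm) <- c(B * Ho * Wo, Cout)
  dW <- array(0, dim(W))
  db <- colSums(dPm)
  dX <- if (need_dX) array(0, d) else NULL
  for (di in 0:2) {
    for (dj in 0:2) {
      Xs <- X[, di + seq_len(Ho), dj + seq_len(Wo), , drop = FALSE]
      dim(Xs) <- c(B * Ho * Wo, Cin)
      dW[di + 1L, dj + 1L, , ] <- crossprod(Xs, dPm)
      if (need_dX) {
        dXs <- dPm %*% t(matrix(W[di + 1L, dj + 1L, , ], Cin, Cout))
        dim(dXs) <- c(B, Ho, Wo, Cin)
        dX[, di + seq_len(Ho), dj + seq_len(Wo), ] <-
          dX[, di + seq_len(Ho), dj + seq_len(Wo), , drop = FALSE] + dXs
      }
    }
  }
  list(dW = dW, db = db, dX = dX)
}

pool_offsets <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))

maxpool_forward <- function(X) {
  d <- dim(X)
  B <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  Ho <- H %/% 2L; Wo <- Wd %/% 2L
  slices <- lapply(pool_offsets, function(o) {
    s <- X[, o[1] + seq(1L, 2L * Ho, by = 2L),
           o[2] + seq(1L, 2L * Wo, by = 2L), , drop = FALSE]
    as.vector(s)
  })
  M <- do.call(cbind, slices)
  arg <- max.col(M, ties.method = "first")
  out <- M[cbind(seq_len(nrow(M)), arg)]
  dim(out) <- c(B, Ho, Wo, C)
  list(out = out, arg = arg, in_dim = d, out_dim = c(B, Ho, Wo, C))
}

maxpool_backward <- function(cache, dOut) {
  dX <- array(0, cache$in_dim)
  Ho <- cache$out_dim[2]; Wo <- cache$out_dim[3]
  dv <- as.vector(dOut)
  for (k in seq_along(pool_offsets)) {
    sel <- cache$arg == k
    if (!any(sel)) next
    o <- pool_offsets[[k]]
    sl <- array(0, cache$out_dim)
    sl[sel] <- dv[sel]
    dX[, o[1] + seq(1L, 2L * Ho, by = 2L),
       o[2] + seq(1L, 2L * Wo, by = 2L), ] <-
      dX[, o[1] + seq(1L, 2L * Ho, by = 2L),
         o[2] + seq(1L, 2L * Wo, by = 2L), , drop = FALSE] + sl
  }
  dX
}

quality_model_init <- function(resolution, conv_channels = c(16L, 32L),
                               dense_hidden = 32L, seed = 1L) {
  R <- as.integer(resolution)
  C1 <- conv_channels[1]; C2 <- conv_channels[2]
  p1 <- (R - 2L) %/% 2L
  p2 <- (p1 - 2L) %/% 2L
  if (p2 < 1L) stop("image too small for two conv+pool blocks")
  flat <- p2 * p2 * C2
  with_seed(substream_seed(seed, "quality"), {
    gl <- function(fan_in, fan_out, n) {
      s <- sqrt(6 / (fan_in + fan_out))
      stats::runif(n, -s, s)
    }
    list(W1 = array(gl(9, 9 * C1, 9 * C1), c(3, 3, 1, C1)), b1 = numeric(C1),
         W2 = array(gl(9 * C1, 9 * C2, 9 * C1 * C2), c(3, 3, C1, C2)),
         b2 = numeric(C2),
         W3 = matrix(gl(flat, dense_hidden, flat * dense_hidden),
                     flat, dense_hidden),
         b3 = numeric(dense_hidden),
         W4 = matrix(gl(dense_hidden, 1, dense_hidden), dense_hidden, 1L),
         b4 = 0)
  })
}

quality_forward <- function(params, X) {
  c1 <- conv_forward(X, params$W1, params$b1)
  m1 <- maxpool_forward(c1$out)
  c2 <- conv_forward(m1$out, params$W2, params$b2)
  m2 <- maxpool_forward(c2$out)
  B <- dim(X)[1]
  flat <- m2$out; dim(flat) <- c(B, prod(m2$out_dim[-1]))
  z3 <- sweep(flat %*% params$W3, 2L, params$b3, `+`)
  a3 <- pmax(z3, 0)
  pred <- as.vector(a3 %*% params$W4 + params$b4)
  list(pred = pred,
       cache = list(c1 = c1, m1 = m1, c2 = c2, m2 = m2, flat = flat,
                    z3 = z3, a3 = a3))
}

quality_backward <- function(params, cache, dpred) {
  dpred <- matrix(dpred, ncol = 1L)
  gW4 <- crossprod(cache$a3, dpred)
  gb4 <- sum(dpred)
  da3 <- dpred %*% t(params$W4)
  dz3 <- da3 * (cache$z3 > 0)
  gW3 <- crossprod(cache$flat, dz3)
  gb3 <- colSums(dz3)
  dflat <- dz3 %*% t(params$W3)
  dim(dflat) <- cache$m2$out_dim
  dp2 <- maxpool_backward(cache$m2, dflat)
  cb2 <- conv_backward(cache$c2, params$W2, dp2, need_dX = TRUE)
  dp1 <- maxpool_backward(cache$m1, cb2$dX)
  cb1 <- conv_backward(cache$c1, params$W1, dp1, need_dX = FALSE)
  list(W1 = cb1$dW, b1 = cb1$db, W2 = cb2$dW, b2 = cb2$db,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

as_image_array <- function(pis) {
  if (is.array(pis) && length(dim(pis)) == 3L) {
    X <- array(pis, c(dim(pis), 1L))
  } else if (is.list(pis)) {
    R <- nrow(pis[[1]])
    X <- array(0, c(length(pis), R, R, 1L))
    for (i in seq_along(pis)) X[i, , , 1L] <- pis[[i]]
  } else stop("pis must be a list of matrices or a [n x R x R] array")
  X
}

#' Fit the image-quality regressor and return quality coefficients
#'
#' Trains a small convolutional network (two 3x3 conv + max-pool blocks,
#' one hidden dense layer, scalar head) to regress a clinical score from a
#' persistence image, using Adam on mean squared error for a fixed number
#' of rounds (500 by default). The per-sample predictions of the trained
#' model are returned as the image quality coefficients. Targets are
#' standardized internally and predictions mapped back to score units.
#'
#' @param pis list of `R x R` images or an `[n, R, R]` array.
#' @param targets numeric clinical scores, one per image (n >= 5).
#' @param epochs training rounds (default 500).
#' @param lr Adam learning rate.
#' @param conv_channels channel widths of the two conv blocks.
#' @param dense_hidden width of the hidden dense layer.
#' @param seed integer seed.
#' @return a `quality_model`: list with `params`, `coefficients` (numeric,
#'   one per sample), `losses` (per-epoch MSE on standardized targets) and
#'   the target scaling.
#' @export
fit_quality_model <- function(pis, targets, epochs = 500L, lr = 1e-3,
                              conv_channels = c(16L, 32L),
                              dense_hidden = 32L, seed = 1L) {
  X <- as_image_array(pis)
  n <- dim(X)[1]
  stopifnot(length(targets) == n, n >= 5, all(is.finite(targets)))
  mu <- mean(targets)
  sd_t <- stats::sd(targets)
  if (!is.finite(sd_t) || sd_t == 0) sd_t <- 1
  y <- (targets - mu) / sd_t
  params <- quality_model_init(dim(X)[2], conv_channels, dense_hidden, seed)
  opt <- adam_state(params)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- quality_forward(params, X)
    loss <- mean((fw$pred - y)^2)
    if (!is.finite(loss)) stop("quality-model training diverged (NaN loss)")
    grads <- quality_backward(params, fw$cache, 2 * (fw$pred - y) / n)
    st <- adam_step(params, grads, opt, lr)
    params <- st$params; opt <- st$state
    losses[ep] <- loss
  }
  final <- quality_forward(params, X)$pred * sd_t + mu
  structure(list(params = params, coefficients = final, losses = losses,
                 target_mean = mu, target_sd = sd_t,
                 resolution = dim(X)[2]),
            class = "quality_model")
}

#' Quality coefficients for new images
#'
#' @param model a fitted `quality_model`.
#' @param pis images as in [fit_quality_model()].
#' @return numeric coefficients in score units.
#' @export
predict_quality <- function(model, pis) {
  X <- as_image_array(pis)
  quality_forward(model$params, X)$pred * model$target_sd + model$target_mean
}

#' Pearson correlation between quality coefficients and clinical scores
#'
#' Pearson r with a two-sided p-value from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}. Errors on zero-variance input.
#'
#' @param coefficients,scores numeric vectors, n >= 3.
#' @param variable optional label for the clinical variable.
#' @param band optional label for the frequency band.
#' @return one-row tibble with `band`, `clinical_variable`, `n`, `r`, `p`.
#' @export
correlate <- function(coefficients, scores, variable = NA_character_,
                      band = NA_character_) {
  stopifnot(length(coefficients) == length(scores),
            length(coefficients) >= 3)
  if (stats::sd(coefficients) == 0 || stats::sd(scores) == 0) {
    stop("undefined correlation: zero variance in input")
  }
  ct <- stats::cor.test(coefficients, scores, method = "pearson",
                        alternative = "two.sided")
  tibble::tibble(band = band, clinical_variable = variable,
                 n = length(scores), r = unname(ct$estimate),
                 p = ct$p.value)
}

#' Band-by-variable correlation table of quality coefficients
#'
#' Fits one quality model per band (supervised by `panss_total`) and
#' correlates its coefficients with each clinical variable, mirroring a
#' bands-by-scores correlation table.
#'
#' @param pi_seqs `pi_sequences` for patient subjects (one image per
#'   subject per band is formed by averaging the subject's windows).
#' @param clinical tibble with `subject_id`, `panss_total`,
#'   `panss_positive`, `panss_negative`.
#' @param epochs,seed passed to [fit_quality_model()].
#' @return tibble with one row per band x clinical variable: `r`, `p`.
#' @export
clinical_correlations <- function(pi_seqs, clinical, epochs = 500L,
                                  seed = 1L) {
  bands <- unique(vapply(pi_seqs, function(e) e$band, character(1)))
  rows <- list()
  for (b in bands) {
    entries <- Filter(function(e) e$band == b &&
                        e$subject_id %in% clinical$subject_id, pi_seqs)
    if (length(entries) < 5) next
    imgs <- lapply(entries, function(e) apply(e$pis, c(2, 3), mean))
    ids <- vapply(entries, function(e) e$subject_id, character(1))
    cl <- clinical[match(ids, clinical$subject_id), ]
    fit <- fit_quality_model(imgs, cl$panss_total, epochs = epochs,
                             seed = substream_seed(seed, b))
    for (v in c("panss_total", "panss_positive", "panss_negative")) {
      rows[[paste(b, v)]] <- correlate(fit$coefficients, cl[[v]],
                                       variable = v, band = b)
    }
  }
  do.call(rbind, rows)
}
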