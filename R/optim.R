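# Generic optimizers over nested parameter lists. Parameters and gradients
# share the same nesting; numeric leaves are updated in place.

map_leaves <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) {
      if (!is.null(b[[nm]])) out[[nm]] <- map_leaves(a[[nm]], b[[nm]], f)
    }
    return(out)
  }
  f(a, b)
}

zero_like <- function(a) {
  if (is.list(a)) return(lapply(a, zero_like))
  if (!is.numeric(a)) return(a)   # structural fields (names, flags) pass through
  a * 0
}

rmsprop_state <- function(params) list(cache = zero_like(params))

# RMSprop: cache <- rho * cache + (1 - rho) * g^2;
#          theta <- theta - lr * g / (sqrt(cache) + eps)
rmsprop_step <- function(params, grads, state, lr, rho = 0.9, eps = 1e-8) {
  state$cache <- map_leaves(state$cache, grads,
                            function(c, g) rho * c + (1 - rho) * g^2)
  params <- local({
    rec <- function(p, g, c) {
      if (is.list(p)) {
        for (nm in names(p)) {
          if (!is.null(g[[nm]])) p[[nm]] <- rec(p[[nm]], g[[nm]], c[[nm]])
        }
        return(p)
      }
      p - lr * g / (sqrt(c) + eps)
    }
    rec(params, grads, state$cache)
  })
  list(params = params, state = state)
}

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_leaves(state$m, grads,
                        function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map_leaves(state$v, grads,
                        function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  rec <- function(p, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (!is.null(m[[nm]])) p[[nm]] <- rec(p[[nm]], m[[nm]], v[[nm]])
      }
      return(p)
    }
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(params = rec(params, state$m, state$v), state = state)
}

check_finite_loss <- function(loss, what) {
  if (!is.finite(loss)) {
    stop(what, " diverged: loss is ", loss,
         " (try a lower learning rate or a different seed)")
  }
  loss
}
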