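# Shared fixtures and independent oracles for the test suite.

# Minimal cohort of recordings with known band amplitudes (for tests that
# only need amplitude metadata, not full signal simulation).
stub_cohort <- function(n_patients, n_controls = 0, seed = 1,
                        theta_amp = NULL) {
  withr::with_seed(seed, {
    recs <- list()
    mk <- function(id, label) {
      amps <- c(Delta = 20, Theta = theta_amp %||% runif(1, 5, 15),
                Alpha = 15, Beta = 5, Gamma = 3)
      topoforecast:::new_eeg_recording(
        id, matrix(rnorm(20), 2, 10), fs = 10, label = label,
        band_amplitudes = amps)
    }
    for (i in seq_len(n_patients)) {
      recs[[sprintf("P%02d", i)]] <- mk(sprintf("P%02d", i), "patient")
    }
    for (i in seq_len(n_controls)) {
      recs[[sprintf("C%02d", i)]] <- mk(sprintf("C%02d", i), "control")
    }
    recs
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fast small synthetic cohort config for pipeline tests.
tiny_cohort_config <- function(...) {
  cohort_config(n_subjects_per_class = 2L, duration_s = 8, fs = 100,
                n_channels = 2L, ...)
}

# Sorts diagrams canonically and compares them feature-for-feature.
expect_diagrams_equal <- function(a, b, tol = 1e-9) {
  expect_equal(nrow(a), nrow(b))
  key <- function(d) d[order(d$dim, d$birth, d$death), ]
  a <- key(a); b <- key(b)
  expect_equal(a$dim, b$dim)
  expect_equal(a$birth, b$birth, tolerance = tol)
  fin <- is.finite(a$death)
  expect_equal(fin, is.finite(b$death))
  expect_equal(a$death[fin], b$death[fin], tolerance = tol)
}

# Independent average-precision oracle: explicit area under the
# step-interpolated precision-recall curve.
ap_bruteforce <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / sum(lab)
  area <- 0
  prev_rec <- 0
  for (k in seq_along(lab)) {
    if (rec[k] > prev_rec) {
      area <- area + (rec[k] - prev_rec) * prec[k]
      prev_rec <- rec[k]
    }
  }
  area
}

# Independent AUC oracle: exhaustive positive/negative pair counting.
auc_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Dense per-node reference for one GAT layer (independent of the package's
# edge-list implementation): explicit loops over nodes and neighbourhoods.
gat_dense_oracle <- function(A, H, layer) {
  n <- nrow(A)
  out <- matrix(0, n, layer$f_out)
  for (k in seq_len(layer$K)) {
    WH <- H %*% layer$W[[k]]
    for (i in seq_len(n)) {
      nbrs <- which(A[i, ])
      e <- vapply(nbrs, function(j) {
        sum(layer$a_dst[[k]] * WH[i, ]) + sum(layer$a_src[[k]] * WH[j, ])
      }, numeric(1))
      l <- ifelse(e > 0, e, layer$leaky_slope * e)
      a <- exp(l - max(l)); a <- a / sum(a)
      for (jj in seq_along(nbrs)) {
        out[i, ] <- out[i, ] + a[jj] * WH[nbrs[jj], ] / layer$K
      }
    }
  }
  switch(layer$activation,
         linear = out,
         elu = ifelse(out > 0, out, exp(pmin(out, 0)) - 1),
         sigmoid = 1 / (1 + exp(-out)))
}

new_pd <- function(birth = numeric(0), death = numeric(0),
                   dim = integer(0)) {
  topoforecast:::new_persistence_diagram(birth, death, dim)
}

one_feature_pd <- function(birth, death, dim = 1L) {
  new_pd(birth = birth, death = death, dim = dim)
}

# Relative error with an absolute floor (finite differences are noisy for
# near-zero gradients).
rel_err <- function(a, b, floor = 1e-6) {
  abs(a - b) / max(abs(a), abs(b), floor)
}
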