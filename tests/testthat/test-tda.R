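test_that("delay embedding enumerates lagged coordinates", {
  pc <- delay_embed(c(0, 1, 2, 3), embed_dim = 2, delay = 1)
  expect_equal(unclass(pc), matrix(c(0, 1, 2, 1, 2, 3), 3, 2),
               ignore_attr = TRUE)

  pc2 <- delay_embed(rep(2, 10), embed_dim = 3, delay = 2)
  expect_equal(nrow(pc2), 10 - (3 - 1) * 2)
  expect_true(all(pc2 == 2))

  # count formula checked against direct enumeration on a long series
  x <- sin(seq_len(1000) / 7)
  pc3 <- delay_embed(x, embed_dim = 3, delay = 4)
  expect_equal(nrow(pc3), 992)
  expect_equal(pc3[17, ], c(x[17], x[21], x[25]))

  expect_error(delay_embed(1:3, embed_dim = 3, delay = 2), "too short")
})

test_that("cloud subsampling is a seeded subset and identity when small", {
  x <- sin(seq_len(1000) / 7)
  cloud <- delay_embed(x, 3, 4)
  sub <- subsample_cloud(cloud, 200, seed = 11)
  expect_equal(nrow(sub), 200)
  expect_true(all(apply(sub, 1, function(r) {
    any(apply(cloud, 1, function(q) all(q == r)))
  })))
  expect_identical(sub, subsample_cloud(cloud, 200, seed = 11))
  expect_false(identical(sub, subsample_cloud(cloud, 200, seed = 12)))
  expect_identical(subsample_cloud(cloud, 2000, seed = 1), cloud)
})

test_that("Rips persistence is exact on worked examples", {
  expect_equal(
    as.data.frame(rips_persistence(matrix(c(0, 0), 1, 2))),
    data.frame(birth = 0, death = Inf, dim = 0L))

  two <- rips_persistence(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE),
                          max_filtration = 10)
  expect_equal(two$birth, c(0, 0))
  expect_equal(two$death, c(5, Inf))

  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  d <- rips_persistence(sq, max_hom_dim = 1)
  h1 <- d[d$dim == 1, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))

  expect_error(rips_persistence(matrix(numeric(0), 0, 2)), "empty")
})

test_that("brute-force oracle matches hand reduction on the triangle", {
  s <- 2
  tr <- matrix(c(0, 0, s, 0, s / 2, s * sqrt(3) / 2), ncol = 2, byrow = TRUE)
  d <- brute_force_persistence(tr, max_hom_dim = 1, max_filtration = 5)
  # three components: two die at the edge scale s, one essential; the
  # filled triangle's loop has zero persistence and is discarded
  expect_equal(d$dim, c(0L, 0L, 0L))
  expect_equal(d$birth, c(0, 0, 0))
  expect_equal(d$death, c(s, s, Inf))
  expect_error(brute_force_persistence(matrix(rnorm(39), 13, 3)), "12")
})

test_that("fast reduction and brute-force oracle agree feature-for-feature", {
  set.seed(404)
  for (i in 1:8) {
    n <- sample(5:10, 1)
    cloud <- matrix(rnorm(n * 3), n, 3)
    expect_diagrams_equal(rips_persistence(cloud, max_hom_dim = 2),
                          brute_force_persistence(cloud, max_hom_dim = 2))
  }
})

test_that("diagrams scale equivariantly and are stable under perturbation", {
  set.seed(7)
  cloud <- matrix(rnorm(24), 8, 3)
  base <- rips_persistence(cloud, max_hom_dim = 1)
  for (c_scale in c(0.5, 3)) {
    scaled <- rips_persistence(cloud * c_scale, max_hom_dim = 1,
                               max_filtration = NULL)
    fin <- is.finite(base$death)
    expect_equal(scaled$birth, base$birth * c_scale, tolerance = 1e-9)
    expect_equal(scaled$death[fin], base$death[fin] * c_scale,
                 tolerance = 1e-9)
  }

  # perturbing every point by <= eps moves every endpoint by <= 2 eps
  eps <- 1e-3
  for (rep in 1:5) {
    pert <- cloud + matrix(runif(24, -eps / sqrt(3), eps / sqrt(3)), 8, 3)
    d2 <- rips_persistence(pert, max_hom_dim = 1,
                           max_filtration = max(dist(cloud)) + 1)
    d1 <- rips_persistence(cloud, max_hom_dim = 1,
                           max_filtration = max(dist(cloud)) + 1)
    # same feature counts per dimension and matched endpoints within 2 eps
    expect_equal(table(d1$dim), table(d2$dim))
    for (dm in unique(d1$dim)) {
      a <- d1[d1$dim == dm, ]; b <- d2[d2$dim == dm, ]
      expect_true(all(abs(sort(a$birth) - sort(b$birth)) <= 2 * eps))
      fa <- sort(a$death[is.finite(a$death)])
      fb <- sort(b$death[is.finite(b$death)])
      expect_true(all(abs(fa - fb) <= 2 * eps))
    }
  }
})

test_that("persistence images integrate kernel mass and stay in range", {
  empty <- new_pd()
  img0 <- diagram_to_pi(empty, resolution = 16)
  expect_equal(dim(img0), c(16L, 16L))
  expect_true(all(img0 == 0))

  d100 <- diagram_to_pi(one_feature_pd(0.5, 1.0))
  expect_equal(dim(d100), c(100L, 100L))

  # pre-normalization mass: sum(pixels) * pixel_area ~ weight * Gaussian
  # mass inside the grid (2-D integration oracle via pnorm)
  birth <- 0.45; death <- 0.75; sigma <- 0.04
  img <- diagram_to_pi(one_feature_pd(birth, death), resolution = 80,
                       sigma = sigma, birth_range = c(0, 1),
                       pers_range = c(0, 1), normalize = FALSE)
  pers <- death - birth
  w <- pers / 1
  mass <- w *
    (pnorm(1, birth, sigma) - pnorm(0, birth, sigma)) *
    (pnorm(1, pers, sigma) - pnorm(0, pers, sigma))
  expect_equal(sum(img) * attr(img, "pixel_area"), mass, tolerance = 0.01)

  # min-max normalization lands in [0, 1]
  imgn <- diagram_to_pi(one_feature_pd(birth, death), resolution = 40,
                        birth_range = c(0, 1), pers_range = c(0, 1))
  expect_true(all(imgn >= 0 & imgn <= 1))
  expect_equal(max(imgn), 1)

  # infinite features and excluded dimensions contribute nothing
  d <- new_pd(birth = c(0, 0.5), death = c(Inf, 0.9), dim = c(0L, 0L))
  expect_true(all(diagram_to_pi(d, resolution = 10, hom_dims = 1) == 0))
})

test_that("persistence images are additive before normalization", {
  a <- one_feature_pd(0.2, 0.6)
  b <- one_feature_pd(0.5, 0.95)
  ab <- new_pd(birth = c(0.2, 0.5), death = c(0.6, 0.95), dim = c(1L, 1L))
  args <- list(resolution = 32, sigma = 0.05, birth_range = c(0, 1),
               pers_range = c(0, 1), normalize = FALSE)
  ia <- do.call(diagram_to_pi, c(list(a), args))
  ib <- do.call(diagram_to_pi, c(list(b), args))
  iab <- do.call(diagram_to_pi, c(list(ab), args))
  expect_equal(unclass(iab), unclass(ia) + unclass(ib), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pooled axis ranges cover every finite high-order feature", {
  set.seed(3)
  diags <- lapply(1:5, function(i) {
    rips_persistence(matrix(rnorm(30), 10, 3), max_hom_dim = 1)
  })
  rg <- pi_axis_ranges(diags, hom_dims = 1)
  for (d in diags) {
    keep <- is.finite(d$death) & d$dim == 1
    if (!any(keep)) next
    expect_true(all(d$birth[keep] >= rg$birth_range[1]))
    expect_true(all(d$birth[keep] <= rg$birth_range[2]))
    expect_true(all(d$death[keep] - d$birth[keep] <= rg$pers_range[2]))
  }
})
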