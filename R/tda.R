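#' Delay embedding of a scalar series
#'
#' Reconstructs a point cloud from a univariate time series by Takens delay
#' embedding: point \eqn{i} is
#' \eqn{(x_i, x_{i+\tau}, \ldots, x_{i+(m-1)\tau})} for embedding dimension
#' \eqn{m} and delay \eqn{\tau} (in samples). The cloud has
#' `length(series) - (embed_dim - 1) * delay` points.
#'
#' @param series numeric vector, the (band-filtered) signal window.
#' @param embed_dim embedding dimension \eqn{m \ge 2}.
#' @param delay delay \eqn{\tau \ge 1} in samples.
#' @return a `point_cloud`: numeric matrix `[n_points x embed_dim]`.
#' @export
#' @examples
#' delay_embed(c(0, 1, 2, 3), embed_dim = 2, delay = 1)
delay_embed <- function(series, embed_dim = 3L, delay = 4L) {
  stopifnot(is.numeric(series), embed_dim >= 2, delay >= 1)
  embed_dim <- as.integer(embed_dim)
  delay <- as.integer(delay)
  span <- (embed_dim - 1L) * delay
  n <- length(series) - span
  if (n < 1L) {
    stop("series too short for embed_dim = ", embed_dim, ", delay = ", delay)
  }
  if (!all(is.finite(series))) stop("series contains non-finite values")
  cloud <- vapply(seq_len(embed_dim) - 1L,
                  function(k) series[seq_len(n) + k * delay],
                  numeric(n))
  cloud <- matrix(cloud, nrow = n, ncol = embed_dim)
  structure(cloud, class = c("point_cloud", "matrix"))
}

#' Choose an embedding delay by average mutual information
#'
#' Returns the lag of the first local minimum of the binned average mutual
#' information of the series, a common heuristic for the delay-embedding lag.
#' Falls back to `max_lag` when no local minimum exists.
#'
#' @param series numeric vector.
#' @param max_lag largest lag examined.
#' @param n_bins number of equal-width histogram bins.
#' @return integer delay in samples.
#' @export
select_delay_ami <- function(series, max_lag = 25L, n_bins = 16L) {
  stopifnot(length(series) > max_lag + 1)
  brk <- seq(min(series), max(series), length.out = n_bins + 1L)
  brk[1] <- brk[1] - 1e-9
  bins <- cut(series, breaks = brk, labels = FALSE)
  ami <- vapply(seq_len(max_lag), function(lag) {
    a <- bins[seq_len(length(bins) - lag)]
    b <- bins[seq_len(length(bins) - lag) + lag]
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    nz <- tab > 0
    sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  }, numeric(1))
  for (lag in seq_len(max_lag - 1L)[-1]) {
    if (ami[lag] < ami[lag - 1L] && ami[lag] <= ami[lag + 1L]) return(lag)
  }
  as.integer(max_lag)
}

#' Deterministic seeded subsample of a point cloud
#'
#' Vietoris-Rips complexity grows steeply with the number of points, so
#' clouds are thinned to at most `max_points` by a seeded uniform subsample
#' without replacement (identity when already small enough).
#'
#' @param cloud `point_cloud` matrix.
#' @param max_points maximum number of points kept (>= 2).
#' @param seed integer seed controlling the subsample.
#' @return a `point_cloud` with at most `max_points` rows.
#' @export
subsample_cloud <- function(cloud, max_points = 200L, seed = 1L) {
  stopifnot(is.matrix(cloud), max_points >= 2)
  n <- nrow(cloud)
  if (n <= max_points) return(cloud)
  keep <- with_seed(seed, sort(sample.int(n, max_points)))
  structure(cloud[keep, , drop = FALSE], class = c("point_cloud", "matrix"))
}

new_persistence_diagram <- function(birth, death, dim) {
  d <- tibble::tibble(birth = as.numeric(birth),
                      death = as.numeric(death),
                      dim = as.integer(dim))
  structure(d, class = c("persistence_diagram", class(d)))
}

#' Vietoris-Rips persistence diagram of a Euclidean point cloud
#'
#' Computes persistent homology of the Vietoris-Rips filtration (Euclidean
#' metric) up to homology dimension `max_hom_dim` by boundary-matrix
#' reduction over Z/2 (compiled backend). Zero-persistence pairs are
#' discarded; essential classes carry `death = Inf`. The default filtration
#' cutoff is the enclosing radius (the smallest max-distance from any point
#' to all others), beyond which no new finite feature in dimension >= 1 can
#' appear.
#'
#' @param cloud `point_cloud` matrix `[n x d]`, n >= 1.
#' @param max_hom_dim largest homology dimension computed (0, 1 or 2).
#' @param max_filtration filtration cutoff; `NULL` for the enclosing radius.
#' @return a `persistence_diagram` tibble with columns `birth`, `death`,
#'   `dim`.
#' @export
#' @examples
#' sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
#' rips_persistence(sq, max_hom_dim = 1)
rips_persistence <- function(cloud, max_hom_dim = 1L, max_filtration = NULL) {
  if (is.null(dim(cloud))) cloud <- matrix(cloud, ncol = 1L)
  if (nrow(cloud) < 1L) stop("empty point cloud")
  stopifnot(max_hom_dim %in% 0:2, all(is.finite(cloud)))
  dm <- as.matrix(stats::dist(cloud))
  if (is.null(max_filtration)) {
    max_filtration <- if (nrow(dm) == 1L) 0 else min(apply(dm, 1L, max))
  }
  raw <- .rips_cpp(dm, as.integer(max_hom_dim), as.numeric(max_filtration))
  diag <- new_persistence_diagram(raw[, 1L], raw[, 2L], raw[, 3L])
  sort_diagram(diag)
}

sort_diagram <- function(diag) {
  ord <- order(diag$dim, diag$birth, diag$death)
  structure(diag[ord, ], class = class(diag))
}

#' Brute-force persistence oracle for tiny clouds
#'
#' Independent reference implementation used to validate
#' [rips_persistence()]: enumerates every simplex up to dimension
#' `max_hom_dim + 1` with `utils::combn()`, orders them by (diameter,
#' dimension), and reduces the boundary matrix over Z/2 with plain R vector
#' operations. Refuses clouds with more than 12 points.
#'
#' @inheritParams rips_persistence
#' @return a `persistence_diagram` tibble.
#' @export
brute_force_persistence <- function(cloud, max_hom_dim = 1L,
                                    max_filtration = NULL) {
  if (is.null(dim(cloud))) cloud <- matrix(cloud, ncol = 1L)
  n <- nrow(cloud)
  if (n < 1L) stop("empty point cloud")
  if (n > 12L) stop("brute-force oracle is restricted to <= 12 points")
  stopifnot(max_hom_dim %in% 0:2)
  dm <- as.matrix(stats::dist(cloud))
  if (is.null(max_filtration)) {
    max_filtration <- if (n == 1L) 0 else min(apply(dm, 1L, max))
  }

  verts <- lapply(seq_len(n), function(i) i)
  simplices <- list(verts)
  for (d in seq_len(max_hom_dim + 1L)) {
    if (n < d + 1L) { simplices[[d + 1L]] <- list(); next }
    cmb <- utils::combn(n, d + 1L, simplify = FALSE)
    keep <- Filter(function(v) max(dm[v, v]) <= max_filtration, cmb)
    simplices[[d + 1L]] <- keep
  }
  all_s <- unlist(simplices, recursive = FALSE)
  dims <- rep(seq_along(simplices) - 1L, vapply(simplices, length, 0L))
  diams <- vapply(all_s, function(v) if (length(v) == 1L) 0 else max(dm[v, v]),
                  numeric(1))
  lex <- vapply(all_s, function(v) paste(sprintf("%03d", v), collapse = ""),
                character(1))
  ord <- order(diams, dims, lex)
  all_s <- all_s[ord]; dims <- dims[ord]; diams <- diams[ord]
  m <- length(all_s)
  key_of <- function(v) paste(v, collapse = "-")
  pos <- new.env(hash = TRUE, parent = emptyenv())
  for (p in seq_len(m)) assign(key_of(all_s[[p]]), p, envir = pos)

  pivot_col <- integer(m)           # row -> column holding that pivot (0 = none)
  stored <- vector("list", m)
  positive <- logical(m)
  paired <- logical(m)
  births <- numeric(0); deaths <- numeric(0); fdims <- integer(0)

  for (p in seq_len(m)) {
    if (dims[p] == 0L) { positive[p] <- TRUE; next }
    v <- all_s[[p]]
    col <- sort(vapply(seq_along(v),
                       function(drop) get(key_of(v[-drop]), envir = pos),
                       integer(1)))
    repeat {
      if (length(col) == 0L) break
      piv <- col[length(col)]
      other <- pivot_col[piv]
      if (other == 0L) break
      u <- c(col, stored[[other]])
      col <- sort(u[!(u %in% u[duplicated(u)])])  # symmetric difference
    }
    if (length(col) == 0L) {
      positive[p] <- TRUE
    } else {
      piv <- col[length(col)]
      pivot_col[piv] <- p
      stored[[p]] <- col
      paired[piv] <- TRUE
      if (diams[p] > diams[piv]) {
        births <- c(births, diams[piv])
        deaths <- c(deaths, diams[p])
        fdims <- c(fdims, dims[piv])
      }
    }
  }
  ess <- which(positive & !paired & dims <= max_hom_dim)
  births <- c(births, diams[ess])
  deaths <- c(deaths, rep(Inf, length(ess)))
  fdims <- c(fdims, dims[ess])
  sort_diagram(new_persistence_diagram(births, deaths, fdims))
}

#' Vectorize a persistence diagram as a persistence image
#'
#' Finite features with homology dimension in `hom_dims` are mapped to
#' (birth, persistence) coordinates; each deposits a Gaussian bump of
#' standard deviation `sigma`, weighted linearly in persistence
#' (weight = persistence / upper persistence range), onto an `R x R` grid
#' of pixel centres spanning `birth_range` x `pers_range`. Rows index the
#' birth axis, columns the persistence axis. With `normalize = TRUE`
#' (default) the accumulated image is min-max scaled to `[0, 1]`
#' (an all-zero image stays zero), so images share the range of the
#' generator's sigmoid output.
#'
#' @param diag a `persistence_diagram`.
#' @param resolution grid side `R` (default 100).
#' @param sigma Gaussian kernel sd; default 0.05 x persistence-axis range.
#' @param hom_dims homology dimensions included (default `c(1, 2)`: the
#'   high-order image of loops and voids).
#' @param birth_range,pers_range axis ranges `c(lo, hi)`; defaults derived
#'   from the diagram (pipelines should pass pooled ranges so images are
#'   comparable across windows).
#' @param normalize min-max scale to `[0, 1]`?
#' @return a `persistence_image`: nonnegative `R x R` matrix with axis
#'   metadata attributes.
#' @export
diagram_to_pi <- function(diag, resolution = 100L, sigma = NULL,
                          hom_dims = c(1L, 2L), birth_range = NULL,
                          pers_range = NULL, normalize = TRUE) {
  stopifnot(resolution >= 2)
  R <- as.integer(resolution)
  keep <- is.finite(diag$death) & diag$dim %in% hom_dims
  b <- diag$birth[keep]
  p <- diag$death[keep] - diag$birth[keep]
  if (is.null(birth_range)) {
    birth_range <- if (length(b)) range(b) + c(-1, 1) * 1e-8 else c(0, 1)
    birth_range[2] <- max(birth_range[2], birth_range[1] + 1e-8)
  }
  if (is.null(pers_range)) {
    pers_range <- if (length(p)) c(0, max(p) + 1e-8) else c(0, 1)
  }
  stopifnot(birth_range[2] > birth_range[1], pers_range[2] > pers_range[1])
  if (is.null(sigma)) sigma <- 0.05 * diff(pers_range)
  stopifnot(sigma > 0)

  bx <- seq(birth_range[1], birth_range[2], length.out = R + 1L)
  px <- seq(pers_range[1], pers_range[2], length.out = R + 1L)
  bc <- (bx[-1] + bx[-(R + 1L)]) / 2   # pixel centres, birth axis (rows)
  pc <- (px[-1] + px[-(R + 1L)]) / 2   # pixel centres, persistence axis (cols)

  img <- matrix(0, R, R)
  if (length(b)) {
    w <- p / pers_range[2]
    for (i in seq_along(b)) {
      img <- img + w[i] * (stats::dnorm(bc, b[i], sigma) %o%
                             stats::dnorm(pc, p[i], sigma))
    }
  }
  if (normalize) {
    mx <- max(img)
    if (mx > 0) img <- (img - min(img)) / (mx - min(img))
  }
  structure(img,
            class = c("persistence_image", "matrix"),
            birth_range = birth_range, pers_range = pers_range,
            sigma = sigma, hom_dims = hom_dims,
            pixel_area = diff(birth_range) / R * diff(pers_range) / R)
}

#' Pooled persistence-image axis ranges over a set of diagrams
#'
#' Computes the (birth, persistence) ranges covering every finite feature of
#' the requested homology dimensions across `diagrams`, padded by `pad`
#' (fraction of span) so mass near the extremes is not clipped. Pipelines
#' freeze these ranges from the training set so images are comparable.
#'
#' @param diagrams list of `persistence_diagram`s.
#' @param hom_dims homology dimensions included.
#' @param pad fractional padding added on each side of the birth axis and
#'   above the persistence axis (persistence axis starts at 0).
#' @return list with `birth_range` and `pers_range`.
#' @export
pi_axis_ranges <- function(diagrams, hom_dims = c(1L, 2L), pad = 0.1) {
  b <- numeric(0); p <- numeric(0)
  for (d in diagrams) {
    keep <- is.finite(d$death) & d$dim %in% hom_dims
    b <- c(b, d$birth[keep])
    p <- c(p, d$death[keep] - d$birth[keep])
  }
  if (!length(b)) return(list(birth_range = c(0, 1), pers_range = c(0, 1)))
  bspan <- max(diff(range(b)), 1e-6)
  list(birth_range = c(min(b) - pad * bspan, max(b) + pad * bspan),
       pers_range = c(0, max(p) * (1 + pad) + 1e-9))
}
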