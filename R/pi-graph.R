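#' Convert a persistence image to a pixel-grid graph
#'
#' Builds the graph the attention layers consume: one node per pixel in
#' row-major order, undirected edges between grid neighbours (4- or
#' 8-neighbourhood) and a self-loop at every node (so each node attends to
#' itself and the attention softmax is defined even for an isolated node).
#' The graph structure depends only on the grid shape; pixel intensities
#' become the single input node feature.
#'
#' @param pi a `persistence_image` (any numeric matrix works).
#' @param neighborhood 4 or 8.
#' @return a `pi_graph`: list with `node_features` (`N x 1` matrix, N = R^2),
#'   `dst`/`src` (directed edge list including both orientations and
#'   self-loops; `src[e]` is a neighbour of `dst[e]`), `grid_shape`,
#'   `n_nodes`.
#' @export
pi_to_graph <- function(pi, neighborhood = 8L) {
  stopifnot(is.matrix(pi), neighborhood %in% c(4L, 8L))
  nr <- nrow(pi); nc <- ncol(pi)
  graph <- grid_graph(nr, nc, neighborhood)
  graph$node_features <- matrix(flatten_pi(pi), ncol = 1L)
  graph
}

# Structure-only grid graph (row-major node ids), cached per shape within a
# session via a package-local environment since it never depends on data.
.graph_cache <- new.env(parent = emptyenv())

grid_graph <- function(nr, nc, neighborhood = 8L) {
  key <- paste(nr, nc, neighborhood, sep = "x")
  hit <- .graph_cache[[key]]
  if (!is.null(hit)) return(hit)
  id <- function(r, c) (r - 1L) * nc + c       # row-major
  offs <- if (neighborhood == 8L) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  rr <- rep(seq_len(nr), each = nc)
  cc <- rep(seq_len(nc), times = nr)
  dst <- src <- vector("list", nrow(offs) + 1L)
  for (o in seq_len(nrow(offs))) {
    r2 <- rr + offs[o, 1]; c2 <- cc + offs[o, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    dst[[o]] <- id(rr[ok], cc[ok])
    src[[o]] <- id(r2[ok], c2[ok])
  }
  dst[[nrow(offs) + 1L]] <- seq_len(nr * nc)   # self-loops
  src[[nrow(offs) + 1L]] <- seq_len(nr * nc)
  dst <- unname(unlist(dst)); src <- unname(unlist(src))
  ord <- order(dst, src)
  g <- structure(list(node_features = NULL, dst = dst[ord], src = src[ord],
                      grid_shape = c(nr, nc), n_nodes = nr * nc,
                      neighborhood = as.integer(neighborhood)),
                 class = "pi_graph")
  .graph_cache[[key]] <- g
  g
}

#' @export
print.pi_graph <- function(x, ...) {
  cat(sprintf("<pi_graph> %d x %d grid, %d nodes, %d directed edges (incl. self-loops), %d-neighbourhood\n",
              x$grid_shape[1], x$grid_shape[2], x$n_nodes, length(x$dst),
              x$neighborhood))
  invisible(x)
}

#' Dense adjacency matrix of a pixel-grid graph
#'
#' Convenience for inspection and tests; symmetric logical matrix with
#' self-loops on the diagonal.
#'
#' @param graph a `pi_graph`.
#' @return logical `N x N` matrix.
#' @export
graph_adjacency <- function(graph) {
  A <- matrix(FALSE, graph$n_nodes, graph$n_nodes)
  A[cbind(graph$dst, graph$src)] <- TRUE
  A
}

#' Flatten a persistence image to a column vector (row-major)
#'
#' @param pi numeric `R x R` matrix.
#' @return numeric vector of length `R^2`, row-major order (matching the
#'   node ordering of [pi_to_graph()]).
#' @export
flatten_pi <- function(pi) {
  stopifnot(is.matrix(pi))
  as.vector(t(pi))
}

#' Reshape a flattened vector back into a persistence image
#'
#' Inverse of [flatten_pi()]: `unflatten_pi(flatten_pi(x), dim(x))` is `x`.
#'
#' @param v numeric vector of length `prod(grid_shape)`.
#' @param grid_shape `c(rows, cols)`.
#' @return numeric matrix of shape `grid_shape`.
#' @export
unflatten_pi <- function(v, grid_shape) {
  if (length(v) != prod(grid_shape)) {
    stop("length ", length(v), " does not match grid ",
         paste(grid_shape, collapse = " x "))
  }
  structure(matrix(v, nrow = grid_shape[1], ncol = grid_shape[2],
                   byrow = TRUE),
            class = c("persistence_image", "matrix"))
}
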