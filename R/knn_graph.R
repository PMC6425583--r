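#' Build a symmetrized kNN graph
#'
#' Connects every cell to its `k` nearest neighbors (exact Euclidean search,
#' ties broken by lowest cell index), symmetrizes by the union of directed
#' relations and weights edges with the chosen kernel. Weights lie in (0, 1].
#'
#' Kernels:
#' \describe{
#'   \item{exponential}{The smooth-kNN weighting of the UMAP family with
#'     local connectivity 1: per cell, the distance to the nearest neighbor
#'     is subtracted and a per-cell bandwidth is solved so the weights sum to
#'     log2(k). Conflicting directed weights are resolved by the maximum.}
#'   \item{adaptive_gaussian}{Diffusion-map style kernel
#'     `exp(-d^2 / (s_i^2 + s_j^2))` with per-cell bandwidth `s_i` equal to
#'     the distance to the ceiling(k/2)-th neighbor.}
#'   \item{unit}{Weight 1 on every edge.}
#' }
#'
#' @param rep A `Representation` (or numeric coordinate matrix, cells in rows).
#' @param k Number of neighbors, `1 <= k < n_cells`.
#' @param kernel One of `"exponential"`, `"adaptive_gaussian"`, `"unit"`.
#' @return An object of class `NeighborGraph`: list with `n_cells`,
#'   `cell_ids`, `edges` (data.frame `i`, `j`, `weight`, `dist` with
#'   `i < j`, 1-based), `k`, `kernel`, `metric`.
#' @export
build_knn_graph <- function(rep, k,
                            kernel = c("exponential", "adaptive_gaussian", "unit")) {
  kernel <- match.arg(kernel)
  coords <- rep_coords(rep)
  n <- nrow(coords)
  if (k < 1 || k >= n) stop("parameter error: need 1 <= k < n_cells")

  nn <- knn_indices(coords, k)
  nn_idx <- nn$idx
  nn_dist <- nn$dist

  w_dir <- switch(kernel,
    unit = matrix(1, n, k),
    exponential = smooth_knn_weights(nn_dist),
    adaptive_gaussian = adaptive_gaussian_weights(nn_dist, nn_idx)
  )

  # union symmetrization, max weight on conflict
  ii <- rep(seq_len(n), k)
  jj <- as.vector(nn_idx)
  ww <- as.vector(w_dir)
  dd <- as.vector(nn_dist)
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  key <- (a - 1) * n + b
  o <- order(key, -ww)
  first <- !duplicated(key[o])
  edges <- data.frame(i = a[o][first], j = b[o][first],
                      weight = ww[o][first], dist = dd[o][first])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL

  ids <- rownames(coords)
  if (is.null(ids)) ids <- sprintf("cell_%d", seq_len(n))
  structure(list(n_cells = n, cell_ids = ids, edges = edges, k = k,
                 kernel = kernel, metric = "euclidean"),
            class = "NeighborGraph")
}

# exact k-nearest-neighbor search by full pairwise distances; distance ties
# broken by lowest cell index
knn_indices <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  idx <- matrix(0L, n, k)
  dist <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(k)]
    idx[i, ] <- ord
    dist[i, ] <- d[i, ord]
  }
  list(idx = idx, dist = dist)
}

# UMAP-family smooth-kNN weights: rho_i = distance to nearest neighbor,
# sigma_i solved by bisection so sum_j exp(-(d_ij - rho_i)_+ / sigma_i) = log2(k).
smooth_knn_weights <- function(nn_dist, n_iter = 64) {
  k <- ncol(nn_dist)
  if (k == 1) return(matrix(1, nrow(nn_dist), 1))
  target <- log2(k)
  w <- matrix(1, nrow(nn_dist), k)
  for (i in seq_len(nrow(nn_dist))) {
    rho <- nn_dist[i, 1]
    dadj <- pmax(nn_dist[i, ] - rho, 0)
    if (all(dadj == 0)) { w[i, ] <- 1; next }
    lo <- 0; hi <- Inf; sigma <- 1
    for (it in seq_len(n_iter)) {
      s <- sum(exp(-dadj / sigma))
      if (abs(s - target) < 1e-6) break
      if (s > target) { hi <- sigma; sigma <- (lo + hi) / 2 }
      else { lo <- sigma; sigma <- if (is.finite(hi)) (lo + hi) / 2 else sigma * 2 }
    }
    w[i, ] <- exp(-dadj / sigma)
  }
  w
}

adaptive_gaussian_weights <- function(nn_dist, nn_idx) {
  k <- ncol(nn_dist)
  sig <- pmax(nn_dist[, ceiling(k / 2)], .Machine$double.eps)
  w <- matrix(0, nrow(nn_dist), k)
  for (i in seq_len(nrow(nn_dist))) {
    sj <- sig[nn_idx[i, ]]
    w[i, ] <- exp(-nn_dist[i, ]^2 / (sig[i]^2 + sj^2))
  }
  w
}

#' @export
print.NeighborGraph <- function(x, ...) {
  cat(sprintf("NeighborGraph: %d cells, %d edges (k = %d, %s kernel)\n",
              x$n_cells, nrow(x$edges), x$k, x$kernel))
  invisible(x)
}

#' Convert a NeighborGraph to an igraph object
#'
#' @param graph A `NeighborGraph`.
#' @param weighted Attach kernel weights as the `weight` edge attribute.
#' @return An undirected `igraph` graph with `n_cells` vertices.
#' @export
as_igraph <- function(graph, weighted = TRUE) {
  g <- igraph::make_empty_graph(n = graph$n_cells, directed = FALSE)
  g <- igraph::add_edges(g, rbind(graph$edges$i, graph$edges$j))
  if (weighted) igraph::E(g)$weight <- graph$edges$weight
  igraph::V(g)$name <- graph$cell_ids
  g
}

#' Construct a NeighborGraph from an edge table
#'
#' Used by tests and readers; validates symmetry conventions (edges stored
#' once with `i < j`, no self loops, positive weights).
#'
#' @param n_cells Number of cells.
#' @param edges Data frame with columns `i`, `j` (1-based) and optionally
#'   `weight` (default 1).
#' @param k Neighbor parameter to record (default `NA`).
#' @param cell_ids Optional identifiers.
#' @param kernel Kernel name to record.
#' @return A `NeighborGraph`.
#' @export
neighbor_graph <- function(n_cells, edges, k = NA_integer_, cell_ids = NULL,
                           kernel = "unit") {
  if (is.null(edges$weight)) edges$weight <- 1
  if (any(edges$i == edges$j)) stop("self loops are not allowed")
  if (any(edges$weight <= 0)) stop("weights must be positive")
  a <- pmin(edges$i, edges$j); b <- pmax(edges$i, edges$j)
  edges <- data.frame(i = a, j = b, weight = edges$weight)
  if (anyDuplicated(edges[, c("i", "j")])) stop("duplicate edges")
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(n_cells))
  structure(list(n_cells = n_cells, cell_ids = cell_ids, edges = edges,
                 k = k, kernel = kernel, metric = "euclidean"),
            class = "NeighborGraph")
}

#' Write a NeighborGraph as a weighted edge list
#'
#' TSV with columns `u`, `v`, `weight`; cell indices are 0-based.
#'
#' @param graph A `NeighborGraph`.
#' @param file Output path; a `.graphml` extension writes GraphML instead.
#' @return Invisibly, the file path.
#' @export
write_neighbor_graph <- function(graph, file) {
  if (grepl("\\.graphml$", file)) {
    igraph::write_graph(as_igraph(graph), file, format = "graphml")
  } else {
    df <- data.frame(u = graph$edges$i - 1L, v = graph$edges$j - 1L,
                     weight = graph$edges$weight)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' Read a NeighborGraph edge list written by [write_neighbor_graph()]
#'
#' @param file TSV path with 0-based `u`, `v` and `weight` columns.
#' @param n_cells Number of cells; inferred from the maximum index when `NULL`.
#' @param cell_ids Optional cell identifiers.
#' @return A `NeighborGraph`.
#' @export
read_neighbor_graph <- function(file, n_cells = NULL, cell_ids = NULL) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  if (is.null(n_cells)) n_cells <- max(df$u, df$v) + 1L
  neighbor_graph(n_cells,
                 data.frame(i = df$u + 1L, j = df$v + 1L, weight = df$weight),
                 cell_ids = cell_ids)
}
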