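#' Force-directed layout of a PAGA graph
#'
#' 2-D Fruchterman-Reingold layout of the thresholded abstracted graph with
#' edge attraction proportional to connectivity. Deterministic given the
#' seed.
#'
#' @param paga A thresholded `PagaGraph`.
#' @param seed Integer seed.
#' @param n_iter Number of layout iterations.
#' @return An object of class `Layout`: list with `positions`
#'   (nodes x 2 matrix with rownames) and `level = "group"`.
#' @export
layout_paga_graph <- function(paga, seed = 0, n_iter = 500) {
  if (is.null(paga$edges_kept)) stop("paga must be thresholded first")
  g <- igraph::make_empty_graph(n = paga$n_groups, directed = FALSE)
  ed <- paga$edges_kept
  if (nrow(ed) > 0) {
    g <- igraph::add_edges(g, rbind(ed$i, ed$j))
    igraph::E(g)$weight <- ed$theta
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  pos <- igraph::layout_with_fr(g, niter = n_iter, grid = "nogrid",
                                weights = if (nrow(ed) > 0) igraph::E(g)$weight else NULL)
  pos <- ensure_distinct_positions(pos)
  rownames(pos) <- paga$group_names
  colnames(pos) <- c("x", "y")
  structure(list(positions = pos, level = "group"), class = "Layout")
}

# nudge coincident nodes apart (can happen for isolated nodes)
ensure_distinct_positions <- function(pos) {
  dup <- duplicated(round(pos, 12))
  if (any(dup)) {
    span <- max(apply(pos, 2, function(c) diff(range(c))), 1)
    idx <- which(dup)
    ang <- 2 * pi * seq_along(idx) / length(idx)
    pos[idx, 1] <- pos[idx, 1] + 0.05 * span * cos(ang)
    pos[idx, 2] <- pos[idx, 2] + 0.05 * span * sin(ang)
  }
  pos
}

#' @export
print.Layout <- function(x, ...) {
  cat(sprintf("Layout: %d %s positions\n", nrow(x$positions), x$level))
  invisible(x)
}

#' Initialize fine positions from a coarse layout
#'
#' Every fine node is placed uniformly at random inside the axis-aligned
#' square centered on its coarse node whose half-edge is half the distance
#' to that node's nearest neighbor in the coarse layout. The distance is
#' measured in the Chebyshev (L-infinity) metric, under which axis-aligned
#' squares are balls, so the rectangles of different coarse nodes are
#' guaranteed non-overlapping.
#'
#' @param coarse_layout A `Layout` of the coarse nodes.
#' @param association Integer/character vector, one entry per fine node,
#'   giving its coarse node (e.g. the `labels` of a `Partitioning`, or a
#'   fine-group -> coarse-node map).
#' @param seed Integer seed.
#' @param level Level tag of the returned layout (default `"cell"`).
#' @return A `Layout` for the fine nodes.
#' @export
init_fine_from_coarse <- function(coarse_layout, association, seed = 0,
                                  level = "cell") {
  pos <- coarse_layout$positions
  idx <- if (is.character(association)) match(association, rownames(pos))
         else as.integer(association)
  if (any(is.na(idx)) || any(idx < 1) || any(idx > nrow(pos))) {
    stop("association refers to coarse nodes without a position")
  }
  half <- coarse_half_edges(pos)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- length(idx)
  out <- cbind(x = pos[idx, 1] + stats::runif(n, -1, 1) * half[idx],
               y = pos[idx, 2] + stats::runif(n, -1, 1) * half[idx])
  rownames(out) <- names(association)
  structure(list(positions = out, level = level), class = "Layout")
}

# half the Chebyshev (L-infinity) distance to the nearest coarse neighbor:
# axis-aligned squares are balls of that metric, so the rectangles of two
# nodes can never overlap
coarse_half_edges <- function(pos) {
  n <- nrow(pos)
  if (n == 1) {
    warning("single coarse node: rectangle half-edge defaults to 1")
    return(1)
  }
  d <- as.matrix(stats::dist(pos, method = "maximum"))
  diag(d) <- Inf
  apply(d, 1, min) / 2
}

#' Coarse positions from a fine layout
#'
#' Places each group at the coordinate-wise median of its members'
#' positions.
#'
#' @param fine_layout A `Layout` covering all cells of `part`.
#' @param part A `Partitioning`.
#' @return A `Layout` at group level.
#' @export
coarse_from_fine <- function(fine_layout, part) {
  pos <- fine_layout$positions
  if (nrow(pos) != length(part$labels)) {
    stop("fine layout does not cover the partitioning")
  }
  out <- matrix(NA_real_, part$n_groups, 2,
                dimnames = list(part$group_names, c("x", "y")))
  for (g in seq_len(part$n_groups)) {
    rows <- pos[part$labels == g, , drop = FALSE]
    out[g, ] <- c(stats::median(rows[, 1]), stats::median(rows[, 2]))
  }
  structure(list(positions = out, level = "group"), class = "Layout")
}

#' Refine a single-cell embedding from an initialization
#'
#' Runs a graph-drawing refinement of the single-cell graph starting from
#' the given positions. `"force_directed"` is a Fruchterman-Reingold
#' iteration (edge attraction weighted by the kernel weights);
#' `"umap_like"` is a lightweight attraction/repulsion scheme in the spirit
#' of cross-entropy embeddings. With `n_iter = 0` the initialization is
#' returned unchanged. Deterministic given the seed.
#'
#' @param graph A `NeighborGraph`.
#' @param init A `Layout` covering all cells.
#' @param method `"force_directed"` or `"umap_like"`.
#' @param n_iter Number of refinement iterations.
#' @param seed Integer seed.
#' @return A `Layout` at cell level.
#' @export
embed_cells <- function(graph, init, method = c("force_directed", "umap_like"),
                        n_iter = 50, seed = 0) {
  method <- match.arg(method)
  pos <- init$positions
  if (nrow(pos) != graph$n_cells) stop("init does not cover all cells")
  if (n_iter == 0) {
    return(structure(list(positions = pos, level = "cell"), class = "Layout"))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  out <- if (method == "force_directed") {
    g <- as_igraph(graph)
    igraph::layout_with_fr(g, coords = pos, niter = n_iter, grid = "nogrid",
                           weights = igraph::E(g)$weight)
  } else {
    umap_like_refine(graph, pos, n_iter)
  }
  rownames(out) <- graph$cell_ids
  colnames(out) <- c("x", "y")
  structure(list(positions = out, level = "cell"), class = "Layout")
}

# simple deterministic attraction/repulsion refinement: attraction along
# graph edges proportional to weight, repulsion from one sampled node per
# cell per iteration, learning rate decaying linearly
umap_like_refine <- function(graph, pos, n_iter) {
  n <- nrow(pos)
  ed <- graph$edges
  for (it in seq_len(n_iter)) {
    lr <- 0.1 * (1 - (it - 1) / n_iter)
    delta <- pos[ed$j, ] - pos[ed$i, ]
    pull <- lr * ed$weight * delta
    for (col in 1:2) {
      pos[, col] <- pos[, col] +
        as.vector(tapply(pull[, col], factor(ed$i, levels = 1:n), sum, default = 0)) -
        as.vector(tapply(pull[, col], factor(ed$j, levels = 1:n), sum, default = 0))
    }
    other <- sample.int(n)
    swap <- other == seq_len(n)
    other[swap] <- (other[swap] %% n) + 1L
    dvec <- pos - pos[other, ]
    dist2 <- rowSums(dvec^2) + 1e-6
    pos <- pos + lr * dvec / (1 + dist2)
  }
  pos
}

#' Write a layout as CSV
#'
#' @param layout A `Layout`.
#' @param file Output CSV path (columns `id`, `x`, `y`).
#' @return Invisibly, the file path.
#' @export
write_layout <- function(layout, file) {
  ids <- rownames(layout$positions)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(layout$positions)))
  df <- data.frame(id = ids, x = layout$positions[, 1], y = layout$positions[, 2])
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
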