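#' Count inter-group edges
#'
#' Tallies, for every pair of groups, the number (or summed kernel weight)
#' of graph edges with one endpoint in each group. Each undirected edge is
#' counted once; the matrix is stored symmetrically with a zero diagonal.
#' Per-group degrees count both endpoints, so a within-group edge
#' contributes 2 to its group's degree.
#'
#' @param graph A `NeighborGraph`.
#' @param part A `Partitioning` covering the graph.
#' @param use_weights Sum kernel weights instead of counting edges.
#' @return An object of class `InterEdgeCounts`: list with `e` (G x G
#'   symmetric inter-edge matrix), `e_total`, `degree` (per-group summed
#'   endpoint count), `n_cells`, `sizes`, `use_weights`.
#' @export
count_inter_edges <- function(graph, part, use_weights = FALSE) {
  if (length(part$labels) != graph$n_cells) {
    stop("partitioning does not cover the graph")
  }
  G <- part$n_groups
  gi <- part$labels[graph$edges$i]
  gj <- part$labels[graph$edges$j]
  w <- if (use_weights) graph$edges$weight else rep(1, nrow(graph$edges))
  e <- matrix(0, G, G)
  deg <- numeric(G)
  for (idx in seq_along(gi)) {
    a <- gi[idx]; b <- gj[idx]
    deg[a] <- deg[a] + w[idx]
    deg[b] <- deg[b] + w[idx]
    if (a != b) {
      e[a, b] <- e[a, b] + w[idx]
      e[b, a] <- e[b, a] + w[idx]
    }
  }
  comp <- igraph::components(as_igraph(graph, weighted = FALSE))$membership
  n_comp <- length(unique(comp))
  cell_deg <- numeric(graph$n_cells)
  for (idx in seq_len(nrow(graph$edges))) {
    cell_deg[graph$edges$i[idx]] <- cell_deg[graph$edges$i[idx]] + w[idx]
    cell_deg[graph$edges$j[idx]] <- cell_deg[graph$edges$j[idx]] + w[idx]
  }
  # per-component, per-group cell counts and summed degrees (for the nulls)
  comp_group_sizes <- matrix(0, n_comp, G)
  comp_group_degree <- matrix(0, n_comp, G)
  for (cell in seq_len(graph$n_cells)) {
    cc <- comp[cell]; gg <- part$labels[cell]
    comp_group_sizes[cc, gg] <- comp_group_sizes[cc, gg] + 1
    comp_group_degree[cc, gg] <- comp_group_degree[cc, gg] + cell_deg[cell]
  }
  structure(list(e = e, e_total = sum(w), degree = deg,
                 n_cells = graph$n_cells, sizes = part$sizes,
                 comp_group_sizes = comp_group_sizes,
                 comp_group_degree = comp_group_degree,
                 component_sizes = tabulate(comp, nbins = n_comp),
                 use_weights = use_weights),
            class = "InterEdgeCounts")
}

#' Expected inter-edge counts under a null model
#'
#' Both nulls randomly reassign edge endpoints within connected components:
#' an endpoint rooted at a cell of component c can only land on another cell
#' of c, which makes the statistic independent of the presence of
#' disconnected clusters. With `n_i^c` the number of group-i cells in
#' component c (of size `n_c`), the default `"knn"` null gives
#' `e_hat_ij = k * sum_c n_i^c * n_j^c / (n_c - 1)`; on a connected graph
#' this is the classic `k * n_i * n_j / (n - 1)`. The `"degrees"` null
#' conditions on the realized summed degrees `d_i^c` instead:
#' `e_hat_ij = sum_c (d_i^c * n_j^c + d_j^c * n_i^c) / (2 * (n_c - 1))`.
#' Pairs confined to different components have expectation 0 (no inter-edge
#' is possible).
#'
#' @param counts An `InterEdgeCounts`.
#' @param k Neighbor parameter of the underlying graph (used by `"knn"`).
#' @param null `"knn"` or `"degrees"`.
#' @return G x G matrix of expected inter-edge counts (zero diagonal).
#' @export
expected_inter_edges <- function(counts, k, null = c("knn", "degrees")) {
  null <- match.arg(null)
  G <- length(counts$sizes)
  eh <- matrix(0, G, G)
  for (cc in seq_along(counts$component_sizes)) {
    nc <- counts$component_sizes[cc]
    if (nc < 2) next
    ns_c <- counts$comp_group_sizes[cc, ]
    eh <- eh + switch(null,
      knn = k * outer(ns_c, ns_c) / (nc - 1),
      degrees = {
        d_c <- counts$comp_group_degree[cc, ]
        (outer(d_c, ns_c) + outer(ns_c, d_c)) / (2 * (nc - 1))
      })
  }
  diag(eh) <- 0
  eh
}

#' PAGA connectivity between partitions (undirected)
#'
#' The connectivity statistic between groups i and j is the ratio of
#' observed inter-edges to the count expected under random edge assignment,
#' capped at 1 so it reads as a confidence:
#' `theta_ij = min(1, e_ij / e_hat_ij)`, and 0 whenever no inter-edge is
#' observed. Pairs of degenerate groups for which the null expects zero
#' edges but edges are observed get connectivity 1 with a warning.
#'
#' @param counts An `InterEdgeCounts` from [count_inter_edges()].
#' @param part The `Partitioning` the counts refer to.
#' @param k Neighbor parameter of the underlying kNN graph.
#' @param null Null model passed to [expected_inter_edges()], or a function
#'   `(counts, k) -> G x G` matrix for custom nulls.
#' @param cap Cap connectivity at 1 (default). Disable for diagnostics.
#' @return An object of class `PagaGraph`: list with `n_groups`, `theta`
#'   (G x G symmetric, zero diagonal, entries in `[0, 1]`), `expected`, `e`,
#'   `group_sizes`, `group_names`, `k`, `threshold` (`NA` until
#'   [threshold_graph()]), `edges_kept` (`NULL` until thresholded),
#'   `tendency` (`NULL` unless a directed abstraction is attached).
#' @export
connectivity_undirected <- function(counts, part, k, null = "knn", cap = TRUE) {
  eh <- if (is.function(null)) null(counts, k) else
    expected_inter_edges(counts, k, null)
  e <- counts$e
  G <- nrow(e)
  theta <- matrix(0, G, G)
  pos <- e > 0
  degen <- pos & eh == 0
  if (any(degen)) {
    warning("expected inter-edge count is zero for some observed pairs; ",
            "setting their connectivity to 1")
    theta[degen] <- 1
  }
  ok <- pos & eh > 0
  theta[ok] <- e[ok] / eh[ok]
  if (cap) theta <- pmin(theta, 1)
  diag(theta) <- 0
  structure(list(n_groups = G, theta = theta, expected = eh, e = e,
                 group_sizes = part$sizes, group_names = part$group_names,
                 k = k, threshold = NA_real_, edges_kept = NULL,
                 tendency = NULL),
            class = "PagaGraph")
}

#' @export
print.PagaGraph <- function(x, ...) {
  kept <- if (is.null(x$edges_kept)) "not thresholded" else
    sprintf("%d edges kept at threshold %g", nrow(x$edges_kept), x$threshold)
  cat(sprintf("PagaGraph: %d groups, %s%s\n", x$n_groups, kept,
              if (!is.null(x$tendency)) ", directed tendency attached" else ""))
  invisible(x)
}

#' Directed abstraction of a velocity graph
#'
#' Aggregates cell-level arrows into a group-level transition tendency:
#' with `f_ij` the count (or weight) of arrows from group i to group j,
#' `t_ij = (f_ij - f_ji) / (f_ij + f_ji)` where any arrows exist, else 0.
#' The result is antisymmetric with values in `[-1, 1]`; its sign gives the
#' orientation of an undirected PAGA edge and its magnitude the confidence
#' in that orientation.
#'
#' @param velocity_graph Data frame of directed edges with columns
#'   `source`, `target` (cell ids or 1-based indices) and optionally
#'   `weight`.
#' @param part A `Partitioning` of the same cells.
#' @param paga Optional undirected `PagaGraph` to attach the tendency to
#'   (returned with `$tendency` filled); otherwise a minimal `PagaGraph`
#'   carrying only the tendency is returned.
#' @param use_weights Sum arrow weights instead of counting arrows.
#' @return A `PagaGraph` with the `tendency` matrix set.
#' @export
connectivity_directed <- function(velocity_graph, part, paga = NULL,
                                  use_weights = FALSE) {
  G <- part$n_groups
  f <- matrix(0, G, G)
  if (is.null(velocity_graph) || nrow(velocity_graph) == 0) {
    warning("empty velocity graph: tendency is all zero")
  } else {
    src <- resolve_cells(velocity_graph$source, part$cell_ids)
    tgt <- resolve_cells(velocity_graph$target, part$cell_ids)
    w <- if (use_weights && !is.null(velocity_graph$weight))
      velocity_graph$weight else rep(1, length(src))
    for (idx in seq_along(src)) {
      a <- part$labels[src[idx]]; b <- part$labels[tgt[idx]]
      if (a != b) f[a, b] <- f[a, b] + w[idx]
    }
  }
  tot <- f + t(f)
  tend <- matrix(0, G, G)
  nz <- tot > 0
  tend[nz] <- (f[nz] - t(f)[nz]) / tot[nz]
  if (is.null(paga)) {
    paga <- structure(list(n_groups = G, theta = matrix(0, G, G),
                           expected = matrix(0, G, G), e = matrix(0, G, G),
                           group_sizes = part$sizes,
                           group_names = part$group_names,
                           k = NA_integer_, threshold = NA_real_,
                           edges_kept = NULL, tendency = NULL),
                      class = "PagaGraph")
  }
  paga$tendency <- tend
  paga
}

resolve_cells <- function(x, cell_ids) {
  if (is.numeric(x)) {
    idx <- as.integer(x)
  } else {
    idx <- match(as.character(x), cell_ids)
  }
  if (any(is.na(idx)) || any(idx < 1) || any(idx > length(cell_ids))) {
    stop("velocity graph refers to cells not in the partitioning")
  }
  idx
}

#' Discard spurious edges by thresholding connectivity
#'
#' Keeps the pairs with observed inter-edges and connectivity at or above
#' the threshold; connectivity values themselves are preserved for
#' reporting.
#'
#' @param paga A `PagaGraph`.
#' @param threshold Value in `[0, 1]`; the default 0.01 discards only
#'   clearly spurious connections.
#' @return The `PagaGraph` with `threshold` set and `edges_kept` filled
#'   (data.frame `i`, `j`, `theta`, `tendency` when available; `i < j`).
#' @export
threshold_graph <- function(paga, threshold = 0.01) {
  if (threshold < 0 || threshold > 1) {
    stop("parameter error: threshold must be in [0, 1]")
  }
  G <- paga$n_groups
  keep <- which(upper.tri(paga$theta) & paga$e > 0 & paga$theta >= threshold,
                arr.ind = TRUE)
  edges <- data.frame(i = keep[, 1], j = keep[, 2],
                      theta = paga$theta[keep])
  if (!is.null(paga$tendency)) edges$tendency <- paga$tendency[keep]
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  paga$threshold <- threshold
  paga$edges_kept <- edges
  paga
}

#' Minimum spanning forest of a PAGA graph
#'
#' Kruskal's algorithm on the thresholded edges with weight
#' `1 / connectivity`, so the tree retains the highest-confidence
#' connections; equal weights are broken by lexicographic `(i, j)` order
#' for determinism. Disconnected components each yield their own tree.
#'
#' @param paga A thresholded `PagaGraph` (an unthresholded one is
#'   thresholded at 0 first).
#' @return An object of class `AbstractionTree`: list with `edges`
#'   (data.frame `i`, `j`, `theta`), `n_groups`,
#'   `weight_used = "inverse_connectivity"`.
#' @export
spanning_tree <- function(paga) {
  if (paga$n_groups < 1) stop("parameter error: empty abstraction")
  if (is.null(paga$edges_kept)) paga <- threshold_graph(paga, 0)
  ed <- paga$edges_kept
  ord <- order(1 / ed$theta, ed$i, ed$j)
  parent <- seq_len(paga$n_groups)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  keep <- logical(nrow(ed))
  for (r in ord) {
    ra <- find(ed$i[r]); rb <- find(ed$j[r])
    if (ra != rb) { parent[ra] <- rb; keep[r] <- TRUE }
  }
  edges <- ed[keep, c("i", "j", "theta"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, n_groups = paga$n_groups,
                 weight_used = "inverse_connectivity"),
            class = "AbstractionTree")
}

#' @export
print.AbstractionTree <- function(x, ...) {
  cat(sprintf("AbstractionTree: %d groups, %d edges (forest of %d trees)\n",
              x$n_groups, nrow(x$edges), x$n_groups - nrow(x$edges)))
  invisible(x)
}

#' Associate groups across two resolutions
#'
#' Maps every fine group to the coarse group containing the majority
#' (plurality) of its cells; ties are broken by the lower coarse id.
#'
#' @param fine,coarse `Partitioning`s of the same cells.
#' @return Data frame with columns `fine`, `coarse`, `overlap` (fraction of
#'   the fine group's cells inside the chosen coarse group).
#' @export
map_resolutions <- function(fine, coarse) {
  if (length(fine$labels) != length(coarse$labels)) {
    stop("partitions cover different numbers of cells")
  }
  out <- data.frame(fine = seq_len(fine$n_groups),
                    coarse = NA_integer_, overlap = NA_real_)
  for (g in seq_len(fine$n_groups)) {
    cells <- which(fine$labels == g)
    tab <- tabulate(coarse$labels[cells], nbins = coarse$n_groups)
    best <- which.max(tab)
    out$coarse[g] <- best
    out$overlap[g] <- tab[best] / length(cells)
  }
  out
}

#' Write a PagaGraph to disk
#'
#' Writes GraphML (node attributes: group label and size; edge attributes:
#' connectivity, expected and observed inter-edge counts, tendency when
#' present), an adjacency CSV of the connectivity matrix, and a JSON
#' summary.
#'
#' @param paga A thresholded `PagaGraph`.
#' @param prefix Output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>_connectivity.csv`, `<prefix>.json`.
#' @return Invisibly, the vector of files written.
#' @export
write_paga <- function(paga, prefix) {
  if (is.null(paga$edges_kept)) paga <- threshold_graph(paga, 0)
  g <- igraph::make_empty_graph(n = paga$n_groups, directed = FALSE)
  ed <- paga$edges_kept
  if (nrow(ed) > 0) g <- igraph::add_edges(g, rbind(ed$i, ed$j))
  igraph::V(g)$name <- paga$group_names
  igraph::V(g)$size <- paga$group_sizes
  if (nrow(ed) > 0) {
    igraph::E(g)$connectivity <- ed$theta
    igraph::E(g)$expected <- paga$expected[cbind(ed$i, ed$j)]
    igraph::E(g)$observed <- paga$e[cbind(ed$i, ed$j)]
    if (!is.null(ed$tendency)) igraph::E(g)$tendency <- ed$tendency
  }
  f1 <- paste0(prefix, ".graphml")
  igraph::write_graph(g, f1, format = "graphml")
  f2 <- paste0(prefix, "_connectivity.csv")
  adj <- as.data.frame(paga$theta)
  names(adj) <- paga$group_names
  utils::write.csv(cbind(group = paga$group_names, adj), f2, row.names = FALSE)
  f3 <- paste0(prefix, ".json")
  summary <- list(n_groups = paga$n_groups,
                  group_sizes = paga$group_sizes,
                  threshold = paga$threshold,
                  n_edges_kept = nrow(ed),
                  edges = ed)
  jsonlite::write_json(summary, f3, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3))
}

#' Read a directed velocity edge list
#'
#' TSV with columns `source_cell`, `target_cell`, `weight`.
#'
#' @param file Path to the TSV.
#' @return Data frame with columns `source`, `target`, `weight` suitable for
#'   [connectivity_directed()].
#' @export
read_velocity_graph <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("source", "target")
  if (is.null(df$weight)) df$weight <- 1
  df
}
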