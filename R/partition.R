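#' Partition a neighbor graph with the Louvain algorithm
#'
#' Runs modularity-optimizing Louvain community detection at the requested
#' resolution on the weighted graph. Groups that come out internally
#' disconnected are split into their connected components, so every group
#' induces a connected subgraph. Deterministic given `seed`.
#'
#' @param graph A `NeighborGraph`.
#' @param resolution Louvain resolution parameter (> 0); higher values give
#'   more, smaller groups.
#' @param seed Integer seed controlling the (randomized) optimization.
#' @return An object of class `Partitioning`: list with `labels` (integer
#'   1..G per cell), `sizes`, `n_groups`, `resolution`, `source`,
#'   `group_names`.
#' @export
partition_graph <- function(graph, resolution = 1.0, seed = 0) {
  if (graph$n_cells < 1) stop("parameter error: empty graph")
  if (resolution <= 0) stop("parameter error: resolution must be > 0")
  g <- as_igraph(graph)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                resolution = resolution)
  labels <- split_disconnected_groups(graph, as.integer(igraph::membership(cl)))
  new_partitioning(labels, graph$cell_ids, resolution = resolution,
                   source = "louvain")
}

# split each group into connected components of its induced subgraph,
# renumbering densely by (group, component-min-cell-index) order
split_disconnected_groups <- function(graph, labels) {
  g <- as_igraph(graph, weighted = FALSE)
  out <- integer(length(labels))
  nxt <- 1L
  for (grp in sort(unique(labels))) {
    cells <- which(labels == grp)
    sub <- igraph::induced_subgraph(g, cells)
    comp <- igraph::components(sub)$membership
    for (cid in sort(unique(comp))) {
      out[cells[comp == cid]] <- nxt
      nxt <- nxt + 1L
    }
  }
  out
}

#' Construct a Partitioning from a label vector
#'
#' Labels are re-encoded to dense group ids 1..G in first-appearance order.
#'
#' @param labels Vector of group labels, one per cell (any type).
#' @param cell_ids Cell identifiers (default `cell_<i>`).
#' @return A `Partitioning` with `source = "external"`.
#' @export
partitioning <- function(labels, cell_ids = NULL) {
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_along(labels))
  raw <- as.character(labels)
  lev <- unique(raw)
  new_partitioning(match(raw, lev), cell_ids, source = "external",
                   group_names = lev)
}

new_partitioning <- function(labels, cell_ids, resolution = NULL,
                             source = "external", group_names = NULL) {
  labels <- as.integer(labels)
  if (any(is.na(labels))) stop("every cell must be labeled")
  sizes <- tabulate(labels)
  if (any(sizes == 0)) stop("empty group in partitioning")
  if (is.null(group_names)) group_names <- as.character(seq_along(sizes))
  structure(list(labels = labels, sizes = sizes, n_groups = length(sizes),
                 cell_ids = cell_ids, resolution = resolution, source = source,
                 group_names = group_names),
            class = "Partitioning")
}

#' @export
print.Partitioning <- function(x, ...) {
  cat(sprintf("Partitioning: %d cells in %d groups (%s%s)\n",
              length(x$labels), x$n_groups, x$source,
              if (!is.null(x$resolution)) sprintf(", resolution %g", x$resolution) else ""))
  invisible(x)
}

#' Ingest an external partition labeling
#'
#' Re-encodes arbitrary labels to dense group ids 1..G in order of first
#' appearance along the graph's cell order. Cells of the graph missing from
#' the table are an error; table entries for unknown cells are dropped with
#' a warning.
#'
#' @param table Either a named vector (names = cell ids) or a two-column
#'   data frame (cell id, group label).
#' @param graph The `NeighborGraph` the labels refer to.
#' @return A `Partitioning` with `source = "external"`.
#' @export
load_partition <- function(table, graph) {
  if (is.data.frame(table)) {
    map <- stats::setNames(as.character(table[[2]]), as.character(table[[1]]))
  } else {
    map <- stats::setNames(as.character(table), names(table))
  }
  unknown <- setdiff(names(map), graph$cell_ids)
  if (length(unknown) > 0) {
    warning(sprintf("ignoring %d labels for cells not in the graph (e.g. %s)",
                    length(unknown), unknown[1]))
    map <- map[setdiff(names(map), unknown)]
  }
  missing <- setdiff(graph$cell_ids, names(map))
  if (length(missing) > 0) {
    stop(sprintf("missing labels for cells: %s",
                 paste(utils::head(missing, 10), collapse = ", ")))
  }
  raw <- unname(map[graph$cell_ids])
  lev <- unique(raw)  # first-appearance order
  labels <- match(raw, lev)
  new_partitioning(labels, graph$cell_ids, source = "external",
                   group_names = lev)
}

#' Write partition labels as a two-column CSV
#'
#' @param part A `Partitioning`.
#' @param file Output CSV path (columns `cell_id`, `group_label`).
#' @return Invisibly, the file path.
#' @export
write_partition <- function(part, file) {
  df <- data.frame(cell_id = part$cell_ids,
                   group_label = part$group_names[part$labels])
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read partition labels written by [write_partition()]
#'
#' @param file CSV path.
#' @param graph The `NeighborGraph` the labels refer to.
#' @return A `Partitioning`.
#' @export
read_partition <- function(file, graph) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  load_partition(df, graph)
}

#' Adjusted mutual information between two labelings
#'
#' AMI under the permutation (hypergeometric) null with arithmetic-mean
#' normalization; 1 for identical partitions (up to relabeling), ~0 for
#' independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return AMI value.
#' @export
adjusted_mutual_information <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  n <- length(a)
  stopifnot(length(b) == n)
  tab <- table(a, b)
  ai <- rowSums(tab); bj <- colSums(tab)
  p <- tab / n
  pa <- ai / n; pb <- bj / n
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  }
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  emi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    lo <- max(0, ai[i] + bj[j] - n); hi <- min(ai[i], bj[j])
    if (hi < 1) next
    for (nij in max(lo, 1):hi) {
      lp <- lchoose(bj[j], nij) + lchoose(n - bj[j], ai[i] - nij) -
        lchoose(n, ai[i])
      emi <- emi + exp(lp) * (nij / n) * log(n * nij / (ai[i] * bj[j]))
    }
  }
  denom <- (ha + hb) / 2 - emi
  if (denom == 0) return(1)
  unname((mi - emi) / denom)
}
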