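#' Geodesic distances over a cell sample
#'
#' All-pairs shortest-path distances between a uniform random sample of
#' cells, with edge lengths derived from the kernel weights. The default
#' length transform `1 - log(w)` maps a weight of 1 to length 1 and grows
#' as similarity decreases; `"neg_log"` uses `-log(w)` clipped below at
#' 1e-12; `"unit"` counts hops. Cells in different components are at
#' infinite distance.
#'
#' @param graph A `NeighborGraph`.
#' @param sample_size Number of cells to sample (capped at `n_cells`).
#' @param seed Integer seed for the sample.
#' @param sample Optional explicit vector of cell indices (overrides
#'   `sample_size`/`seed`); use it to evaluate two spaces on the same cells.
#' @param edge_length `"one_minus_log"`, `"neg_log"` or `"unit"`.
#' @return An object of class `GeodesicDistances`: list with `D` (symmetric
#'   matrix, `Inf` across components), `sample_ids`, `sample_idx`,
#'   `edge_length`.
#' @export
geodesic_distances <- function(graph, sample_size = 500, seed = 0,
                               sample = NULL,
                               edge_length = c("one_minus_log", "neg_log", "unit")) {
  edge_length <- match.arg(edge_length)
  if (is.null(sample)) {
    if (sample_size > graph$n_cells) sample_size <- graph$n_cells
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    sample <- sort(sample.int(graph$n_cells, sample_size))
  }
  g <- as_igraph(graph)
  len <- switch(edge_length,
    one_minus_log = 1 - log(graph$edges$weight),
    neg_log = pmax(-log(graph$edges$weight), 1e-12),
    unit = rep(1, nrow(graph$edges))
  )
  D <- igraph::distances(g, v = sample, to = sample, weights = len)
  dimnames(D) <- list(graph$cell_ids[sample], graph$cell_ids[sample])
  structure(list(D = D, sample_ids = graph$cell_ids[sample],
                 sample_idx = sample, edge_length = edge_length),
            class = "GeodesicDistances")
}

#' KL_geo: geodesic-divergence embedding faithfulness
#'
#' Compares the distribution of geodesic distances along the data manifold
#' in the high-dimensional space with the one in the embedding. Distances
#' over the pairs finite in both spaces are transformed (identity by
#' default, optionally a Gaussian kernel) and normalized to probability
#' distributions P (high-dimensional) and Q (embedding); the score is
#' `D_KL(P || Q)` (optionally symmetrized). It is 0 when the two distance
#' matrices are proportional, and grows as the embedding distorts the
#' global topology.
#'
#' @param high,emb `GeodesicDistances` over the same sampled cells.
#' @param transform `"identity"` or `"gaussian"` (kernel of the distances,
#'   bandwidth = median finite distance of each space).
#' @param symmetric Return `(KL(P||Q) + KL(Q||P)) / 2`.
#' @return Non-negative scalar divergence.
#' @export
kl_geo <- function(high, emb, transform = c("identity", "gaussian"),
                   symmetric = FALSE) {
  transform <- match.arg(transform)
  if (!identical(high$sample_ids, emb$sample_ids)) {
    stop("the two geodesic distance sets use different cell samples")
  }
  ut <- upper.tri(high$D)
  dh <- high$D[ut]
  de <- emb$D[ut]
  ok <- is.finite(dh) & is.finite(de)
  if (!any(ok)) stop("no cell pair is connected in both spaces: KL_geo undefined")
  dh <- dh[ok]; de <- de[ok]
  if (transform == "gaussian") {
    hh <- stats::median(dh[dh > 0]); he <- stats::median(de[de > 0])
    dh <- exp(-dh^2 / (2 * hh^2))
    de <- exp(-de^2 / (2 * he^2))
  }
  p <- dh / sum(dh)
  q <- de / sum(de)
  kl <- function(p, q) {
    nz <- p > 0
    sum(p[nz] * log(p[nz] / pmax(q[nz], 1e-300)))
  }
  if (symmetric) (kl(p, q) + kl(q, p)) / 2 else kl(p, q)
}

#' Compare two abstracted topologies by their path sets
#'
#' For every pair of leaf nodes (degree <= 1; all node pairs when the
#' reference has fewer than two leaves) in the reference graph, the
#' shortest path is computed in the reference and, between the associated
#' nodes, in the inferred graph, and the two paths are checked for
#' step-wise consistency. Because a group of one graph can straddle
#' several groups of the other, the association is multi-valued: each node
#' is associated with every node of the other graph it shares cells with,
#' ranked by the minimum of the two relative overlaps. The longer of the
#' two paths is translated into association sets and the shorter path must
#' step through those sets in order (contiguous repeats collapsed) for the
#' pair to count as consistent. Pairs disconnected in both graphs are
#' consistent; pairs disconnected in exactly one are not. The score is the
#' fraction of consistent pairs.
#'
#' @param reference Reference topology: a thresholded `PagaGraph`, an
#'   `AbstractionTree`, or a data frame of node-pair edges with attribute
#'   `n_groups` (or a list with `edges`, `n_groups`).
#' @param inferred A thresholded `PagaGraph` (or `AbstractionTree`).
#' @param ref_labels,inf_labels Cell-level group labels (integer vectors or
#'   `Partitioning`s over the same cells) placing every cell in a node of
#'   the reference and the inferred graph respectively; they define the
#'   association between the two node sets.
#' @return An object of class `TopologyScore`: list with `score` (fraction
#'   of consistent leaf pairs), `n_path_pairs`, `per_pair` detail data
#'   frame.
#' @export
topology_path_score <- function(reference, inferred, ref_labels, inf_labels) {
  ref <- as_topology_graph(reference)
  inf_g <- as_topology_graph(inferred)
  if (inherits(ref_labels, "Partitioning")) ref_labels <- ref_labels$labels
  if (inherits(inf_labels, "Partitioning")) inf_labels <- inf_labels$labels
  if (length(ref_labels) != length(inf_labels)) {
    stop("label vectors cover different numbers of cells")
  }
  nr <- igraph::vcount(ref)
  ni <- igraph::vcount(inf_g)
  ov <- matrix(0, nr, ni)
  tab <- table(factor(ref_labels, levels = seq_len(nr)),
               factor(inf_labels, levels = seq_len(ni)))
  ov[, ] <- as.numeric(tab)
  asso_ref <- association_sets(ov)            # ref node -> ranked inferred
  asso_inf <- association_sets(t(ov))         # inferred node -> ranked ref

  degs <- igraph::degree(ref)
  leaves <- which(degs <= 1)
  if (length(leaves) < 2) leaves <- seq_len(nr)
  if (length(leaves) < 2) {
    # single-node reference: no path pair can be violated
    return(structure(list(score = 1, n_path_pairs = 0,
                          per_pair = data.frame(a = integer(0),
                                                b = integer(0),
                                                consistent = logical(0))),
                     class = "TopologyScore"))
  }
  pairs <- utils::combn(leaves, 2)

  detail <- data.frame(a = pairs[1, ], b = pairs[2, ], consistent = NA)
  for (pidx in seq_len(ncol(pairs))) {
    a <- pairs[1, pidx]; b <- pairs[2, pidx]
    ea <- if (length(asso_ref[[a]]) > 0) asso_ref[[a]][1] else NA_integer_
    eb <- if (length(asso_ref[[b]]) > 0) asso_ref[[b]][1] else NA_integer_
    ref_path <- as.integer(suppressWarnings(
      igraph::shortest_paths(ref, a, b)$vpath[[1]]))
    if (is.na(ea) || is.na(eb)) { detail$consistent[pidx] <- FALSE; next }
    inf_path <- as.integer(suppressWarnings(
      igraph::shortest_paths(inf_g, ea, eb)$vpath[[1]]))
    if (length(ref_path) == 0 || length(inf_path) == 0) {
      # consistent only when unreachable in both graphs
      detail$consistent[pidx] <- length(ref_path) == 0 && length(inf_path) == 0
      next
    }
    if (length(ref_path) >= length(inf_path)) {
      mapped <- asso_ref[ref_path]
      compare <- inf_path
    } else {
      mapped <- asso_inf[inf_path]
      compare <- ref_path
    }
    detail$consistent[pidx] <- steps_consistent(compare, mapped)
  }
  structure(list(score = mean(detail$consistent),
                 n_path_pairs = ncol(pairs), per_pair = detail),
            class = "TopologyScore")
}

# ranked multi-valued association: for each row group, the column groups it
# shares cells with, ordered by decreasing min(overlap/row_size,
# overlap/col_size); ties broken by lower id
association_sets <- function(ov) {
  row_sz <- rowSums(ov)
  col_sz <- colSums(ov)
  lapply(seq_len(nrow(ov)), function(r) {
    cand <- which(ov[r, ] > 0)
    if (length(cand) == 0) return(integer(0))
    score <- pmin(ov[r, cand] / row_sz[r], ov[r, cand] / col_sz[cand])
    cand[order(-score, cand)]
  })
}

# does the shorter path `compare` step through the association sets of the
# longer mapped path in order? a step (l -> l') matches at position ip when
# l is in the set at ip, l' in the set at ip + 1, and every set skipped
# since the previous match also contains l
steps_consistent <- function(compare, mapped) {
  if (length(compare) < 2) return(TRUE)
  ip_progress <- 0L   # position of the previous match; next match must be later
  for (il in seq_len(length(compare) - 1)) {
    l <- compare[il]; l_next <- compare[il + 1]
    found <- FALSE
    for (ip in seq_along(mapped)) {
      if (ip <= ip_progress) next
      if (!(l %in% mapped[[ip]])) next
      if (ip + 1 > length(mapped) || !(l_next %in% mapped[[ip + 1]])) next
      hist_ok <- TRUE
      if (ip > ip_progress + 1) {
        for (iip in seq(ip - 1, ip_progress + 1)) {
          if (!(l %in% mapped[[iip]])) { hist_ok <- FALSE; break }
        }
      }
      if (hist_ok) { found <- TRUE; ip_progress <- ip; break }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

# paths in an abstracted graph follow high-confidence edges: edge length is
# the inverse connectivity when theta is available, 1 otherwise
as_topology_graph <- function(x) {
  if (inherits(x, "PagaGraph")) {
    if (is.null(x$edges_kept)) stop("PagaGraph must be thresholded first")
    ed <- x$edges_kept; n <- x$n_groups
  } else if (inherits(x, "AbstractionTree")) {
    ed <- x$edges; n <- x$n_groups
  } else if (is.data.frame(x)) {
    n <- attr(x, "n_groups")
    if (is.null(n)) n <- max(x[[1]], x[[2]])
    ed <- data.frame(i = x[[1]], j = x[[2]])
  } else if (is.list(x) && !is.null(x$edges)) {
    ed <- x$edges; n <- x$n_groups
  } else {
    stop("cannot interpret topology object")
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(ed) > 0) {
    g <- igraph::add_edges(g, rbind(ed$i, ed$j))
    igraph::E(g)$weight <- if (is.null(ed$theta)) rep(1, nrow(ed)) else
      1 / ed$theta
  }
  g
}

#' @export
print.TopologyScore <- function(x, ...) {
  cat(sprintf("TopologyScore: %.3f over %d leaf pair(s)\n",
              x$score, x$n_path_pairs))
  invisible(x)
}

#' KL_geo between a high-dimensional graph and a 2-D layout
#'
#' Convenience wrapper: samples cells once, computes geodesics on the
#' high-dimensional kNN graph, builds a kNN graph of the same `k` on the
#' layout coordinates and computes geodesics there, then returns
#' [kl_geo()].
#'
#' @param graph High-dimensional `NeighborGraph`.
#' @param layout A `Layout` of the same cells.
#' @param sample_size,seed Sampling controls (shared by both spaces).
#' @param ... Passed to [kl_geo()].
#' @return Scalar divergence.
#' @export
kl_geo_layout <- function(graph, layout, sample_size = 500, seed = 0, ...) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- graph$n_cells
  sample <- sort(sample.int(n, min(sample_size, n)))
  high <- geodesic_distances(graph, sample = sample)
  emb_graph <- build_knn_graph(layout$positions, k = graph$k,
                               kernel = graph$kernel)
  emb_graph$cell_ids <- graph$cell_ids
  emb <- geodesic_distances(emb_graph, sample = sample)
  kl_geo(high, emb, ...)
}

#' Write a metrics list as JSON
#'
#' @param metrics Named list of scalar metrics.
#' @param file Output JSON path.
#' @return Invisibly, the file path.
#' @export
write_metrics <- function(metrics, file) {
  jsonlite::write_json(metrics, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
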