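#' Random-walk transition matrix of a neighbor graph
#'
#' Builds the row-stochastic transition matrix of the kernel-weighted graph.
#' With `density_normalize = TRUE` (the diffusion-maps alpha = 1 convention)
#' the kernel is first divided by the product of node degrees so the walk
#' reflects geometry rather than sampling density. Isolated nodes become
#' absorbing self-loops and are flagged with a warning.
#'
#' @param graph A `NeighborGraph` with positive weights.
#' @param density_normalize Apply the alpha = 1 density correction.
#' @return An object of class `TransitionMatrix`: list with `values`
#'   (n x n row-stochastic matrix), `sym` (the symmetric conjugate used for
#'   spectral computations), `components` (connected-component id per cell),
#'   `n_components`, `cell_ids`.
#' @export
transition_matrix <- function(graph, density_normalize = TRUE) {
  n <- graph$n_cells
  W <- matrix(0, n, n)
  ed <- graph$edges
  W[cbind(ed$i, ed$j)] <- ed$weight
  W[cbind(ed$j, ed$i)] <- ed$weight
  deg <- rowSums(W)
  isolated <- deg == 0
  if (any(isolated)) {
    warning(sprintf("%d isolated node(s): treated as absorbing self-loops",
                    sum(isolated)))
    W[cbind(which(isolated), which(isolated))] <- 1
    deg <- rowSums(W)
  }
  K <- if (density_normalize) W / outer(deg, deg) else W
  z <- rowSums(K)
  Tmat <- K / z
  sym <- K / outer(sqrt(z), sqrt(z))
  comp <- igraph::components(as_igraph(graph, weighted = FALSE))$membership
  structure(list(values = Tmat, sym = sym, components = as.integer(comp),
                 n_components = length(unique(comp)), cell_ids = graph$cell_ids),
            class = "TransitionMatrix")
}

#' @export
print.TransitionMatrix <- function(x, ...) {
  cat(sprintf("TransitionMatrix: %d cells, %d connected component(s)\n",
              nrow(x$values), x$n_components))
  invisible(x)
}

#' Spectral decomposition of the transition matrix
#'
#' Full symmetric eigendecomposition of the conjugate `sym` matrix, which
#' shares eigenvalues with the transition matrix. The unit eigenspace
#' (eigenvalue 1) has dimension equal to the number of connected
#' components; eigenvalues numerically close to (but below) 1 are reported
#' via a message since they indicate weakly connected structure.
#'
#' @param tm A `TransitionMatrix`.
#' @param unit_tol Eigenvalues above `1 - unit_tol` count as the unit
#'   eigenspace.
#' @return List of class `SpectralDecomposition` with `values` (descending),
#'   `vectors` (orthonormal columns, symmetric basis), `unit_dim`.
#' @export
spectral_decomposition <- function(tm, unit_tol = 1e-10) {
  es <- eigen(tm$sym, symmetric = TRUE)
  unit <- es$values > 1 - unit_tol
  unit_dim <- sum(unit)
  if (unit_dim != tm$n_components) {
    warning(sprintf("unit eigenspace dimension %d != number of components %d",
                    unit_dim, tm$n_components))
  }
  near <- es$values <= 1 - unit_tol & es$values > 0.9994
  if (any(near)) {
    message(sprintf("%d eigenvalue(s) close to 1 (max %.6f): weakly connected structure",
                    sum(near), max(es$values[near])))
  }
  structure(list(values = es$values, vectors = es$vectors, unit_dim = unit_dim),
            class = "SpectralDecomposition")
}

#' Diffusion pseudotime distances from a root cell
#'
#' Within the root's connected component, the distance to cell y is the
#' Euclidean distance between the rows of the accumulated transition matrix
#' `M = sum_l lambda_l / (1 - lambda_l) phi_l phi_l^T`, built from the
#' spectrum of the symmetric conjugate transition matrix with the entire
#' unit eigenspace excluded (together with any eigenvalue -1 modes of
#' bipartite graphs, for which the accumulated walk diverges) and truncated
#' to the leading `n_comps` non-unit eigenpairs. By orthonormality this
#' equals
#' `sqrt(sum_l (lambda_l/(1-lambda_l))^2 (phi_l(root) - phi_l(y))^2)`.
#' Cells in other components are assigned `Inf`.
#'
#' @param tm A `TransitionMatrix`.
#' @param root Root cell: integer index or cell id.
#' @param n_comps Number of non-unit eigenpairs used (default 10); values
#'   larger than available are truncated with a warning. Use
#'   `n_comps = Inf` for the full spectrum.
#' @return An object of class `DptResult`: list with `root`, `d`
#'   (named numeric, `Inf` outside the root's component), `n_comps_used`,
#'   `unit_dim`, `components`.
#' @export
dpt_distance <- function(tm, root, n_comps = 10) {
  n <- nrow(tm$values)
  iroot <- if (is.character(root)) match(root, tm$cell_ids) else as.integer(root)
  if (is.na(iroot) || iroot < 1 || iroot > n) stop("invalid root cell")
  sd <- spectral_decomposition(tm)
  # exclude the unit eigenspace (one eigenvalue 1 per component) and, on
  # bipartite graphs, the eigenvalue -1 modes for which the accumulated
  # random walk diverges
  non_unit <- which(abs(sd$values) <= 1 - 1e-10)
  avail <- length(non_unit)
  use <- min(n_comps, avail)
  if (is.finite(n_comps) && n_comps > avail) {
    warning(sprintf("n_comps truncated from %d to %d available non-unit eigenpairs",
                    n_comps, avail))
  }
  sel <- non_unit[seq_len(use)]
  lam <- sd$values[sel]
  fac <- lam / (1 - lam)
  phi <- sd$vectors[, sel, drop = FALSE]
  diffs <- sweep(-phi, 2, phi[iroot, ], "+")      # phi(root) - phi(y)
  d <- sqrt(as.vector((diffs^2) %*% fac^2))
  d[iroot] <- 0
  d[tm$components != tm$components[iroot]] <- Inf
  names(d) <- tm$cell_ids
  structure(list(root = tm$cell_ids[iroot], root_index = iroot, d = d,
                 n_comps_used = use, unit_dim = sd$unit_dim,
                 components = tm$components),
            class = "DptResult")
}

#' @export
print.DptResult <- function(x, ...) {
  cat(sprintf("DptResult: root %s, %d finite / %d cells (%d eigenpairs)\n",
              x$root, sum(is.finite(x$d)), length(x$d), x$n_comps_used))
  invisible(x)
}

#' Pick a root cell within a named group
#'
#' Follows the convention of choosing the cell with the extremal first
#' diffusion component inside a user-designated progenitor group.
#'
#' @param tm A `TransitionMatrix`.
#' @param part A `Partitioning`.
#' @param group Group id (integer) or group name.
#' @return Integer cell index.
#' @export
select_root <- function(tm, part, group) {
  g <- if (is.character(group)) match(group, part$group_names) else as.integer(group)
  if (is.na(g) || g < 1 || g > part$n_groups) stop("unknown group")
  sd <- spectral_decomposition(tm)
  first <- which(sd$values <= 1 - 1e-10)[1]
  psi1 <- sd$vectors[, first]
  cells <- which(part$labels == g)
  cells[which.max(abs(psi1[cells] - stats::median(psi1)))]
}

#' Trace gene expression along a PAGA path
#'
#' Concatenates the cells of an ordered sequence of connected groups,
#' ordering cells within each group by their diffusion pseudotime from the
#' root, and reports per-cell expression of the requested genes together
#' with a sliding-window mean curve per gene.
#'
#' @param paga A thresholded `PagaGraph` (consecutive path groups must be
#'   connected in `edges_kept`).
#' @param path Ordered vector of group ids (or group names).
#' @param part The `Partitioning` defining group membership.
#' @param dpt A `DptResult`; all path cells must have finite distance.
#' @param expr Expression matrix (`CountMatrix` or matrix, cells x genes).
#' @param genes Gene ids or column indices to trace.
#' @param window Sliding-window width for smoothing;
#'   default `max(5, floor(n_path_cells / 50))`.
#' @return Data frame with columns `rank`, `cell_id`, `group`, `d`, one
#'   column per gene, and one smoothed `<gene>_smooth` column per gene.
#' @export
trace_path <- function(paga, path, part, dpt, expr, genes, window = NULL) {
  if (is.character(path)) path <- match(path, paga$group_names)
  if (any(is.na(path))) stop("unknown group in path")
  if (is.null(paga$edges_kept)) stop("paga must be thresholded first")
  if (length(path) > 1) {
    for (s in seq_len(length(path) - 1)) {
      a <- min(path[s], path[s + 1]); b <- max(path[s], path[s + 1])
      hit <- paga$edges_kept$i == a & paga$edges_kept$j == b
      if (!any(hit)) {
        stop(sprintf("path groups %d and %d are not connected in the abstraction",
                     path[s], path[s + 1]))
      }
    }
  }
  x <- as_count_values(expr)
  gi <- if (is.numeric(genes)) as.integer(genes) else match(genes, colnames(x))
  if (any(is.na(gi))) stop("unknown gene(s) requested")

  cells <- integer(0)
  for (g in path) {
    members <- which(part$labels == g)
    if (any(!is.finite(dpt$d[members]))) {
      stop(sprintf("group %d is disconnected from the root's component; cannot order by d", g))
    }
    cells <- c(cells, members[order(dpt$d[members], members)])
  }
  n <- length(cells)
  out <- data.frame(rank = seq_len(n),
                    cell_id = part$cell_ids[cells],
                    group = part$group_names[part$labels[cells]],
                    d = unname(dpt$d[cells]))
  if (is.null(window)) window <- max(5, floor(n / 50))
  for (idx in seq_along(gi)) {
    vals <- x[cells, gi[idx]]
    nm <- colnames(x)[gi[idx]]
    out[[nm]] <- vals
    out[[paste0(nm, "_smooth")]] <- running_mean(vals, window)
  }
  out
}

running_mean <- function(x, w) {
  n <- length(x)
  w <- max(1, min(w, n))
  half <- floor(w / 2)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Write DPT distances as CSV
#'
#' Infinite distances (cells disconnected from the root) are written as
#' `"inf"`.
#'
#' @param dpt A `DptResult`.
#' @param file Output CSV path (columns `cell_id`, `component`, `d`).
#' @return Invisibly, the file path.
#' @export
write_dpt <- function(dpt, file) {
  d_chr <- ifelse(is.finite(dpt$d), format(dpt$d, digits = 15, trim = TRUE), "inf")
  df <- data.frame(cell_id = names(dpt$d), component = dpt$components, d = d_chr)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
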