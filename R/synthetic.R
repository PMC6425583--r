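#' Segment topology constructors
#'
#' A segment topology is the ground-truth graph whose nodes are trajectory
#' segments and whose edges join segments sharing a branch point. Helpers:
#' `linear_topology(n)` is a chain of `n` segments, `y_topology()` one
#' branch point with three segments, `double_branch_topology()` two branch
#' points with five segments.
#'
#' @param n_segments Number of segments.
#' @param edges Two-column matrix/data frame of segment pairs
#'   (parent, child); may have zero rows for isolated segments.
#' @return An object of class `segment_topology`: list with `n_segments`
#'   and `edges` (data.frame `i`, `j`).
#' @export
segment_topology <- function(n_segments, edges = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(i = integer(0), j = integer(0))
  } else {
    edges <- data.frame(i = as.integer(edges[[1]]), j = as.integer(edges[[2]]))
  }
  if (NROW(edges) > 0 && (max(edges$i, edges$j) > n_segments || min(edges$i, edges$j) < 1)) {
    stop("edge refers to unknown segment")
  }
  structure(list(n_segments = as.integer(n_segments), edges = edges),
            class = "segment_topology")
}

#' @rdname segment_topology
#' @export
linear_topology <- function(n_segments) {
  if (n_segments == 1) return(segment_topology(1))
  segment_topology(n_segments,
                   data.frame(i = seq_len(n_segments - 1), j = 2:n_segments))
}

#' @rdname segment_topology
#' @export
y_topology <- function() segment_topology(3, data.frame(i = c(1, 1), j = c(2, 3)))

#' @rdname segment_topology
#' @export
double_branch_topology <- function() {
  segment_topology(5, data.frame(i = c(1, 1, 2, 2), j = c(2, 3, 4, 5)))
}

#' Simulate a tree-structured expression manifold
#'
#' Each segment is a straight line in gene space: a per-segment direction
#' vector with per-gene standard deviation `segment_length`, continuous at
#' branch points (a child segment starts where its parent ends). Cells are
#' sampled uniformly along their segment and perturbed with isotropic
#' Gaussian noise of per-gene sd `noise_sd`. Trees of a forest are placed
#' far apart so they are genuinely disconnected. Ground truth (segment,
#' normalized arc-length time, topology) is recorded.
#'
#' Units: `segment_length` is the scale of a single gene's dynamic range
#' along one segment, so the default `noise_sd = 0.3 * segment_length`
#' makes the per-gene noise 30% of a gene's signal range.
#'
#' @param topology A `segment_topology` (see [y_topology()]).
#' @param cells_per_segment Cells sampled on each segment.
#' @param n_genes Gene-space dimension.
#' @param noise_sd Per-gene Gaussian noise sd; default
#'   `0.3 * segment_length`.
#' @param seed Integer seed.
#' @param segment_length Per-gene scale of a segment's expression change.
#' @param emit `"continuous"` (default; values on a processed scale) or
#'   `"poisson"` (counts drawn around an exponentiated, rescaled signal,
#'   for exercising count preprocessing).
#' @return An object of class `SimulatedDataset`: list with `expr`
#'   (`CountMatrix`), `true_topology` (`segment_topology`), `true_branch`,
#'   `true_time` (in `[0, 1]`), `true_arrows` (`NULL` until
#'   [simulate_arrows()]), `seed`, `params`.
#' @export
simulate_tree <- function(topology, cells_per_segment = 200, n_genes = 50,
                          noise_sd = NULL, seed = 0, segment_length = 1,
                          emit = c("continuous", "poisson")) {
  emit <- match.arg(emit)
  if (!inherits(topology, "segment_topology")) stop("topology must be a segment_topology")
  if (cells_per_segment < 1 || n_genes < 1 || segment_length <= 0) {
    stop("parameter error: generator parameters must be positive")
  }
  if (is.null(noise_sd)) noise_sd <- 0.3 * segment_length
  if (noise_sd < 0) stop("parameter error: noise_sd must be >= 0")

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  S <- topology$n_segments
  adj <- vector("list", S)
  for (r in seq_len(NROW(topology$edges))) {
    i <- topology$edges$i[r]; j <- topology$edges$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  dirs <- matrix(stats::rnorm(S * n_genes, sd = segment_length), S, n_genes)
  starts <- matrix(NA_real_, S, n_genes)
  depth <- rep(NA_real_, S)

  # breadth-first placement per tree; successive trees offset far apart
  tree_id <- integer(S)
  visited <- logical(S)
  n_tree <- 0L
  tree_sep <- 10 * segment_length * sqrt(n_genes) * (S + 1)
  for (root in seq_len(S)) {
    if (visited[root]) next
    n_tree <- n_tree + 1L
    offset_dir <- stats::rnorm(n_genes)
    offset_dir <- offset_dir / sqrt(sum(offset_dir^2))
    starts[root, ] <- (n_tree - 1) * tree_sep * offset_dir
    depth[root] <- 0
    queue <- root
    visited[root] <- TRUE
    tree_id[root] <- n_tree
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (visited[nb]) next
        starts[nb, ] <- starts[cur, ] + dirs[cur, ]
        depth[nb] <- depth[cur] + 1
        visited[nb] <- TRUE
        tree_id[nb] <- n_tree
        queue <- c(queue, nb)
      }
    }
  }

  n_cells <- S * cells_per_segment
  t_local <- stats::runif(n_cells)
  branch <- rep(seq_len(S), each = cells_per_segment)
  x <- starts[branch, , drop = FALSE] + t_local * dirs[branch, , drop = FALSE]
  if (noise_sd > 0) {
    x <- x + matrix(stats::rnorm(n_cells * n_genes, sd = noise_sd),
                    n_cells, n_genes)
  }
  time_raw <- depth[branch] + t_local
  true_time <- if (max(time_raw) > 0) time_raw / max(time_raw) else time_raw

  if (emit == "poisson") {
    z <- (x - min(x)) / max(max(x) - min(x), .Machine$double.eps)
    x <- matrix(stats::rpois(length(z), lambda = exp(3 * z)), nrow(z), ncol(z))
  }
  rownames(x) <- sprintf("cell_%04d", seq_len(n_cells))
  colnames(x) <- sprintf("gene_%03d", seq_len(n_genes))
  expr <- count_matrix(x, processed = (emit == "continuous"))

  params <- list(cells_per_segment = cells_per_segment, n_genes = n_genes,
                 noise_sd = noise_sd, segment_length = segment_length,
                 emit = emit)
  structure(list(expr = expr, true_topology = topology, true_branch = branch,
                 true_time = true_time, true_arrows = NULL, seed = seed,
                 params = params),
            class = "SimulatedDataset")
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat(sprintf("SimulatedDataset: %d cells x %d genes, %d segment(s)%s\n",
              nrow(x$expr), ncol(x$expr), x$true_topology$n_segments,
              if (!is.null(x$true_arrows)) sprintf(", %d arrows", nrow(x$true_arrows)) else ""))
  invisible(x)
}

#' Append a disconnected cluster to a simulated dataset
#'
#' Adds an isotropic Gaussian blob far from the manifold (default offset
#' 10x the manifold diameter), leaving the original cells untouched. The
#' ground-truth topology gains an isolated node.
#'
#' @param ds A `SimulatedDataset`.
#' @param n_cells Number of blob cells.
#' @param offset Distance of the blob center from the data centroid;
#'   default 10x the manifold diameter.
#' @param sd Per-gene sd of the blob (default: the dataset's `noise_sd`).
#' @param seed Integer seed.
#' @return The augmented `SimulatedDataset` (blob cells get the new
#'   segment id and `true_time = 0`).
#' @export
add_disconnected_cluster <- function(ds, n_cells = 100, offset = NULL,
                                     sd = NULL, seed = 0) {
  x <- as_count_values(ds$expr)
  n_genes <- ncol(x)
  rng <- apply(x, 2, range)
  diameter <- sqrt(sum((rng[2, ] - rng[1, ])^2))
  if (is.null(offset)) offset <- 10 * diameter
  if (is.null(sd)) sd <- ds$params$noise_sd
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  centroid <- colMeans(x)
  dir <- stats::rnorm(n_genes)
  dir <- dir / sqrt(sum(dir^2))
  center <- centroid + offset * dir
  blob <- matrix(stats::rnorm(n_cells * n_genes, sd = sd), n_cells, n_genes)
  blob <- sweep(blob, 2, center, "+")
  rownames(blob) <- sprintf("blob_%04d", seq_len(n_cells))
  colnames(blob) <- colnames(x)

  new_seg <- ds$true_topology$n_segments + 1L
  ds$true_topology <- segment_topology(new_seg, ds$true_topology$edges)
  ds$expr <- count_matrix(rbind(x, blob), processed = TRUE)
  ds$true_branch <- c(ds$true_branch, rep(new_seg, n_cells))
  ds$true_time <- c(ds$true_time, rep(0, n_cells))
  ds$params$blob <- list(n_cells = n_cells, offset = offset, sd = sd,
                         seed = seed)
  ds
}

#' Simulate a ground-truth velocity graph
#'
#' Runs an exact kNN search on the expression matrix and emits one arrow
#' per directed neighbor relation (`n_cells * k` arrows, the shape of a
#' cell-level transition graph), oriented from the cell with lower true
#' time to the one with higher true time and flipped independently with
#' probability `flip_rate`.
#'
#' @param ds A `SimulatedDataset`.
#' @param k Neighbors for the underlying kNN search.
#' @param flip_rate Probability in `[0, 0.5]` of reversing an arrow.
#' @param seed Integer seed.
#' @return The `SimulatedDataset` with `true_arrows` set (data frame
#'   `source`, `target`, `weight`).
#' @export
simulate_arrows <- function(ds, k = 15, flip_rate = 0, seed = 0) {
  if (flip_rate < 0 || flip_rate > 0.5) {
    stop("parameter error: flip_rate must be in [0, 0.5]")
  }
  nn <- knn_indices(as_count_values(ds$expr), k)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ii <- rep(seq_len(nrow(nn$idx)), ncol(nn$idx))
  jj <- as.vector(nn$idx)
  fwd <- ds$true_time[ii] <= ds$true_time[jj]
  src <- ifelse(fwd, ii, jj)
  tgt <- ifelse(fwd, jj, ii)
  flip <- stats::runif(length(src)) < flip_rate
  tmp <- src[flip]; src[flip] <- tgt[flip]; tgt[flip] <- tmp
  ds$true_arrows <- data.frame(source = src, target = tgt, weight = 1)
  ds$params$arrows <- list(k = k, flip_rate = flip_rate, seed = seed)
  ds
}

#' Write a simulated dataset to disk
#'
#' Expression as CSV (or MTX with `format = "mtx"`), ground truth as JSON
#' (topology, per-cell segment and time) and arrows, when present, as TSV.
#'
#' @param ds A `SimulatedDataset`.
#' @param prefix Output path prefix.
#' @param format `"csv"` or `"mtx"` for the expression matrix.
#' @return Invisibly, the vector of files written.
#' @export
write_simulated <- function(ds, prefix, format = c("csv", "mtx")) {
  format <- match.arg(format)
  f_expr <- paste0(prefix, if (format == "mtx") "_expr.mtx" else "_expr.csv")
  write_counts(ds$expr, f_expr)
  f_truth <- paste0(prefix, "_truth.json")
  truth <- list(n_segments = ds$true_topology$n_segments,
                topology_edges = ds$true_topology$edges,
                cell_id = rownames(ds$expr),
                segment = ds$true_branch,
                time = ds$true_time,
                seed = ds$seed,
                params = ds$params)
  jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, digits = NA)
  files <- c(f_expr, f_truth)
  if (!is.null(ds$true_arrows)) {
    f_arr <- paste0(prefix, "_arrows.tsv")
    arr <- data.frame(source_cell = rownames(ds$expr)[ds$true_arrows$source],
                      target_cell = rownames(ds$expr)[ds$true_arrows$target],
                      weight = ds$true_arrows$weight)
    utils::write.table(arr, f_arr, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f_arr)
  }
  invisible(files)
}
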