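#' Pipeline configuration
#'
#' Validates and bundles all parameters of the end-to-end workflow. Defaults
#' are the package's standard settings: 15 neighbors with the exponential
#' kernel on 10 principal components, Louvain at resolution 1, connectivity
#' threshold 0.01.
#'
#' @param k Neighbors for the kNN graph.
#' @param kernel Edge kernel (see [build_knn_graph()]).
#' @param n_comps Number of principal components.
#' @param resolution Louvain resolution.
#' @param threshold Connectivity threshold for [threshold_graph()].
#' @param n_dcs Non-unit eigenpairs for [dpt_distance()].
#' @param seed Master seed for all randomized stages.
#' @param root Optional root cell id (or index) enabling the pseudotime
#'   stage.
#' @param preprocess `NULL` to accept the expression matrix as already
#'   processed, or a [preprocess_config()] to run count preprocessing.
#' @param do_embedding Compute PAGA layout and PAGA-initialized single-cell
#'   embedding.
#' @param embed_iter Refinement iterations for [embed_cells()].
#' @return A validated list of class `RunConfig`.
#' @export
paga_config <- function(k = 15, kernel = "exponential", n_comps = 10,
                        resolution = 1.0, threshold = 0.01, n_dcs = 10,
                        seed = 0, root = NULL, preprocess = NULL,
                        do_embedding = TRUE, embed_iter = 50) {
  if (k < 1) stop("validation error: k must be >= 1")
  if (!kernel %in% c("exponential", "adaptive_gaussian", "unit")) {
    stop("validation error: unknown kernel")
  }
  if (n_comps < 2) stop("validation error: n_comps must be >= 2")
  if (resolution <= 0) stop("validation error: resolution must be > 0")
  if (threshold < 0 || threshold > 1) {
    stop("validation error: threshold must be in [0, 1]")
  }
  structure(list(k = k, kernel = kernel, n_comps = n_comps,
                 resolution = resolution, threshold = threshold,
                 n_dcs = n_dcs, seed = seed, root = root,
                 preprocess = preprocess, do_embedding = do_embedding,
                 embed_iter = embed_iter),
            class = "RunConfig")
}

#' Run the abstraction workflow in memory
#'
#' Expression -> PCA -> kNN graph -> Louvain partition -> connectivity ->
#' thresholded PAGA graph. The compact core used by [run_paga()], the
#' benchmark harness and the test-suite.
#'
#' @param expr Expression matrix (`CountMatrix` or matrix; processed unless
#'   `config$preprocess` is set).
#' @param config A [paga_config()].
#' @param partition Optional externally supplied `Partitioning` (skips
#'   Louvain).
#' @return List with `rep`, `graph`, `partition`, `paga` (thresholded).
#' @export
paga_workflow <- function(expr, config = paga_config(), partition = NULL) {
  if (!is.null(config$preprocess)) {
    expr <- preprocess_counts(expr, config$preprocess)
  }
  n_comps <- min(config$n_comps, min(dim(as_count_values(expr))) - 1)
  rep <- compute_representation(expr, n_comps = n_comps, seed = config$seed)
  graph <- build_knn_graph(rep, k = config$k, kernel = config$kernel)
  if (is.null(partition)) {
    partition <- partition_graph(graph, resolution = config$resolution,
                                 seed = config$seed)
  }
  counts <- count_inter_edges(graph, partition)
  paga <- connectivity_undirected(counts, partition, k = config$k)
  paga <- threshold_graph(paga, config$threshold)
  list(rep = rep, graph = graph, partition = partition, paga = paga)
}

#' Run the full PAGA workflow and write all artifacts
#'
#' Executes the workflow of [paga_workflow()], plus layouts and (when a
#' root is configured) pseudotime, writing every artifact into `outdir`:
#' neighbor graph edge list, partition CSV, PAGA GraphML/CSV/JSON, layout
#' CSVs, DPT CSV, the run log and a verbatim copy of the configuration.
#' Rerunning with the same configuration reproduces identical outputs.
#'
#' @param expr Expression input: a `CountMatrix`/matrix, or a path to a
#'   CSV/TSV table readable by [read_counts_dense()].
#' @param outdir Output directory (created if needed).
#' @param config A [paga_config()].
#' @param partition_file Optional CSV of external labels (cell_id, label).
#' @param velocity_file Optional TSV of directed velocity edges.
#' @return Invisibly, a list with the in-memory results and `outdir`.
#' @export
run_paga <- function(expr, outdir, config = paga_config(),
                     partition_file = NULL, velocity_file = NULL) {
  t0 <- Sys.time()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_add <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s (check inputs and configuration)",
                   name, conditionMessage(e)), call. = FALSE)
    })
  }

  if (is.character(expr)) expr <- stage("read", function() read_counts_dense(expr))
  log_add("input: %d cells x %d genes; seed %d", nrow(expr), ncol(expr),
          config$seed)

  res <- stage("workflow", function() paga_workflow(expr, config))
  graph <- res$graph; part <- res$partition; paga <- res$paga

  if (!is.null(partition_file)) {
    part <- stage("partition", function() read_partition(partition_file, graph))
    counts <- count_inter_edges(graph, part)
    paga <- threshold_graph(connectivity_undirected(counts, part, k = config$k),
                            config$threshold)
    res$partition <- part; res$paga <- paga
  }
  log_add("graph: %d edges (k = %d, %s); partition: %d groups (resolution %g)",
          nrow(graph$edges), config$k, config$kernel, part$n_groups,
          config$resolution)
  log_add("paga: %d / %d candidate edges kept at threshold %g",
          nrow(paga$edges_kept), sum(paga$e > 0) / 2, config$threshold)

  if (!is.null(velocity_file)) {
    vel <- stage("velocity", function() read_velocity_graph(velocity_file))
    paga <- connectivity_directed(vel, part, paga = paga)
    res$paga <- paga
    log_add("velocity: %d arrows abstracted", nrow(vel))
  }

  write_neighbor_graph(graph, file.path(outdir, "neighbor_graph.tsv"))
  write_partition(part, file.path(outdir, "partition.csv"))
  write_paga(paga, file.path(outdir, "paga"))

  if (config$do_embedding) {
    coarse <- stage("layout", function()
      layout_paga_graph(paga, seed = config$seed))
    init <- init_fine_from_coarse(coarse, part$labels, seed = config$seed)
    rownames(init$positions) <- graph$cell_ids
    emb <- stage("embedding", function()
      embed_cells(graph, init, n_iter = config$embed_iter, seed = config$seed))
    write_layout(coarse, file.path(outdir, "layout_groups.csv"))
    write_layout(emb, file.path(outdir, "layout_cells.csv"))
    res$coarse_layout <- coarse; res$cell_layout <- emb
    log_add("embedding: %d refinement iterations", config$embed_iter)
  }

  if (!is.null(config$root)) {
    tm <- stage("pseudotime", function() transition_matrix(graph))
    dpt <- stage("pseudotime", function()
      dpt_distance(tm, config$root, n_comps = config$n_dcs))
    write_dpt(dpt, file.path(outdir, "dpt.csv"))
    res$dpt <- dpt
    log_add("dpt: root %s, %d reachable cells", dpt$root,
            sum(is.finite(dpt$d)))
  }

  cfg_out <- config
  cfg_out$preprocess <- if (is.null(config$preprocess)) NULL else
    unclass(config$preprocess)
  jsonlite::write_json(unclass(cfg_out), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  summary <- list(n_cells = graph$n_cells, n_groups = part$n_groups,
                  n_edges_kept = nrow(paga$edges_kept),
                  threshold = paga$threshold, seed = config$seed)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_add("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  writeLines(log_lines, file.path(outdir, "run.log"))
  res$outdir <- outdir
  invisible(res)
}

#' Robustness benchmark: resolution sweep on simulated data
#'
#' Simulates a tree dataset, runs the workflow over a grid of Louvain
#' resolutions and seeds, and reports (a) the topology score of every run
#' against the ground truth, (b) the pairwise topology agreement between
#' runs and the pairwise partition agreement (adjusted mutual information).
#' The abstracted topology being more stable across the sweep than the
#' partitionings themselves is the expected outcome.
#'
#' @param topology A `segment_topology` to simulate.
#' @param resolutions Numeric vector of Louvain resolutions.
#' @param seeds Integer vector of seeds (used for both the simulation noise
#'   and the clustering of each run, offset per run).
#' @param config Base [paga_config()] (resolution and seed are overridden
#'   per run).
#' @param sim_seed Seed of the simulated dataset.
#' @param ... Passed to [simulate_tree()].
#' @return List of class `BenchmarkReport`: `runs` (one row per run:
#'   resolution, seed, n_groups, topology score vs truth), `pairwise`
#'   (topology agreement and AMI for every pair of runs), `summary`
#'   (medians).
#' @export
run_benchmark <- function(topology = y_topology(),
                          resolutions = c(0.3, 0.5, 1, 2, 3),
                          seeds = 0:3, config = paga_config(),
                          sim_seed = 0, ...) {
  ds <- simulate_tree(topology, seed = sim_seed, ...)
  truth_edges <- ds$true_topology$edges
  attr(truth_edges, "n_groups") <- ds$true_topology$n_segments
  true_part_labels <- ds$true_branch

  grid <- expand.grid(resolution = resolutions, seed = seeds)
  runs <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cfg <- config
    cfg$resolution <- grid$resolution[r]
    cfg$seed <- grid$seed[r]
    res <- paga_workflow(ds$expr, cfg)
    truth_part <- partitioning(true_part_labels, rownames(ds$expr))
    ts <- topology_path_score(truth_edges, res$paga, truth_part,
                              res$partition)
    runs[[r]] <- list(resolution = grid$resolution[r], seed = grid$seed[r],
                      n_groups = res$partition$n_groups, score = ts$score,
                      partition = res$partition, paga = res$paga)
  }
  run_df <- data.frame(resolution = vapply(runs, `[[`, 0, "resolution"),
                       seed = vapply(runs, `[[`, 0, "seed"),
                       n_groups = vapply(runs, `[[`, 0, "n_groups"),
                       topology_score_vs_truth = vapply(runs, `[[`, 0, "score"))

  n_runs <- length(runs)
  pairs <- utils::combn(n_runs, 2)
  pw <- data.frame(run_a = pairs[1, ], run_b = pairs[2, ],
                   topology_agreement = NA_real_, ami = NA_real_)
  for (p in seq_len(ncol(pairs))) {
    a <- runs[[pairs[1, p]]]; b <- runs[[pairs[2, p]]]
    pw$topology_agreement[p] <-
      topology_path_score(a$paga, b$paga, a$partition, b$partition)$score
    pw$ami[p] <- adjusted_mutual_information(a$partition$labels,
                                             b$partition$labels)
  }
  structure(list(runs = run_df, pairwise = pw,
                 summary = list(
                   median_score_vs_truth = stats::median(run_df$topology_score_vs_truth),
                   median_topology_agreement = stats::median(pw$topology_agreement),
                   median_ami = stats::median(pw$ami))),
            class = "BenchmarkReport")
}

#' @export
print.BenchmarkReport <- function(x, ...) {
  cat(sprintf(paste0("BenchmarkReport: %d runs\n",
                     "  median topology score vs truth: %.3f\n",
                     "  median pairwise topology agreement: %.3f\n",
                     "  median pairwise partition AMI: %.3f\n"),
              nrow(x$runs), x$summary$median_score_vs_truth,
              x$summary$median_topology_agreement, x$summary$median_ami))
  invisible(x)
}

#' Write a benchmark report
#'
#' @param report A `BenchmarkReport`.
#' @param prefix Path prefix; writes `<prefix>_runs.tsv`,
#'   `<prefix>_pairwise.tsv`, `<prefix>_summary.json`.
#' @return Invisibly, the files written.
#' @export
write_benchmark <- function(report, prefix) {
  f1 <- paste0(prefix, "_runs.tsv")
  utils::write.table(report$runs, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- paste0(prefix, "_pairwise.tsv")
  utils::write.table(report$pairwise, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  f3 <- paste0(prefix, "_summary.json")
  jsonlite::write_json(report$summary, f3, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3))
}
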