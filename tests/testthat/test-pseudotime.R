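test_that("transition matrices are row-stochastic with component block structure", {
  # two-node single edge: deterministic swap
  g <- neighbor_graph(2, data.frame(i = 1, j = 2))
  tm <- transition_matrix(g)
  expect_equal(tm$values, matrix(c(0, 1, 1, 0), 2, 2))

  # disconnected pair of edges: block diagonal, two components
  g2 <- neighbor_graph(4, data.frame(i = c(1, 3), j = c(2, 4)))
  tm2 <- transition_matrix(g2)
  expect_equal(tm2$n_components, 2)
  expect_equal(tm2$values[1:2, 3:4], matrix(0, 2, 2))

  # weighted triangle: rows sum to 1, entries match the hand computation
  g3 <- neighbor_graph(3, data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                                     weight = c(0.5, 0.2, 1)))
  tm3 <- transition_matrix(g3)
  expect_equal(unname(rowSums(tm3$values)), rep(1, 3), tolerance = 1e-10)
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5; W[1, 3] <- W[3, 1] <- 0.2; W[2, 3] <- W[3, 2] <- 1
  q <- rowSums(W)
  K <- W / outer(q, q)
  expect_equal(tm3$values, K / rowSums(K), tolerance = 1e-12)

  # isolated node becomes an absorbing self-loop, flagged
  g4 <- neighbor_graph(3, data.frame(i = 1, j = 2))
  expect_warning(tm4 <- transition_matrix(g4), "isolated")
  expect_equal(tm4$values[3, 3], 1)
})

test_that("the unit eigenspace dimension equals the number of components", {
  set.seed(51)
  blobs <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 50), 10, 2),
                 matrix(rnorm(20, -50), 10, 2))
  g <- build_knn_graph(blobs, k = 3)
  tm <- transition_matrix(g)
  sd <- spectral_decomposition(tm)
  expect_equal(sd$unit_dim, tm$n_components)
  expect_equal(sd$unit_dim, 3)
})

test_that("cells outside the root's component get infinite distance", {
  g <- neighbor_graph(5, data.frame(i = c(1, 2, 4), j = c(2, 3, 5)))
  tm <- transition_matrix(g)
  d <- dpt_distance(tm, root = 1, n_comps = Inf)
  expect_equal(unname(d$d[1]), 0)
  expect_true(all(is.finite(d$d[1:3])))
  expect_true(all(is.infinite(d$d[4:5])))
  # root symmetry within the component
  d3 <- dpt_distance(tm, root = 3, n_comps = Inf)
  expect_equal(unname(d$d[3]), unname(d3$d[1]), tolerance = 1e-12)
})

test_that("distances match the dense accumulated-transition oracle", {
  set.seed(52)
  for (rep_i in 1:3) {
    pts <- matrix(rnorm(36), 18, 2)
    g <- build_knn_graph(pts, k = 3, kernel = "adaptive_gaussian")
    tm <- transition_matrix(g)
    if (tm$n_components > 1) next
    d <- dpt_distance(tm, root = 1, n_comps = Inf)
    es <- eigen(tm$sym, symmetric = TRUE)
    keep <- abs(es$values) <= 1 - 1e-10
    M <- es$vectors[, keep] %*%
      diag(es$values[keep] / (1 - es$values[keep])) %*% t(es$vectors[, keep])
    oracle <- sqrt(colSums((M[1, ] - t(M))^2))
    expect_equal(unname(d$d), oracle, tolerance = 1e-8)
  }
})

test_that("distances increase monotonically along a path graph", {
  g <- neighbor_graph(5, data.frame(i = 1:4, j = 2:5))
  tm <- transition_matrix(g)
  d <- dpt_distance(tm, root = 1, n_comps = Inf)
  expect_true(all(diff(d$d) > 0))
})

test_that("the distance is a pseudometric within a component", {
  set.seed(53)
  pts <- matrix(rnorm(30), 15, 2)
  g <- build_knn_graph(pts, k = 4)
  tm <- transition_matrix(g)
  if (tm$n_components == 1) {
    D <- unname(vapply(1:15, function(r) dpt_distance(tm, r, n_comps = Inf)$d,
                       numeric(15)))
    expect_equal(D, t(D), tolerance = 1e-10)
    for (x in 1:15) for (y in 1:15) for (z in 1:15) {
      expect_lte(D[x, y], D[x, z] + D[z, y] + 1e-10)
    }
  }
})

test_that("diffusion distance rank-agrees with mean commute distance", {
  # on small manifold-structured graphs (the intended regime) the two
  # random-walk distances order cells nearly identically
  for (s in 1:3) {
    ds <- simulate_tree(linear_topology(2), cells_per_segment = 60, seed = s)
    g <- build_knn_graph(unclass(ds$expr), k = 5, kernel = "unit")
    tm <- transition_matrix(g, density_normalize = FALSE)
    n <- g$n_cells
    root <- which.min(ds$true_time)
    d <- dpt_distance(tm, root, n_comps = Inf)
    W <- matrix(0, n, n)
    W[cbind(g$edges$i, g$edges$j)] <- g$edges$weight
    W <- W + t(W)
    Lp <- MASS::ginv(diag(rowSums(W)) - W)
    commute <- vapply(seq_len(n),
                      function(y) Lp[root, root] + Lp[y, y] - 2 * Lp[root, y],
                      numeric(1))
    expect_gt(cor(d$d[-root], commute[-root], method = "spearman"), 0.9)
  }
})

test_that("n_comps beyond the spectrum truncates with a warning", {
  g <- neighbor_graph(4, data.frame(i = 1:3, j = 2:4))
  tm <- transition_matrix(g)
  expect_warning(d <- dpt_distance(tm, 1, n_comps = 10), "truncated")
  # the path graph is bipartite: besides the unit eigenvalue, the -1 mode
  # is excluded too, leaving 2 usable eigenpairs
  expect_equal(d$n_comps_used, 2)
})

test_that("path tracing orders cells by distance and screens bad paths", {
  set.seed(55)
  ds <- simulate_tree(linear_topology(2), cells_per_segment = 120, seed = 8)
  res <- paga_workflow(ds$expr, paga_config(seed = 8))
  tm <- transition_matrix(res$graph)
  root <- which.min(ds$true_time)
  dpt <- suppressMessages(dpt_distance(tm, root))
  # pick the path visiting all groups along the spanning tree from the
  # root group to the farthest leaf group (groups are ordered by the chain)
  med_d <- vapply(seq_len(res$partition$n_groups), function(g)
    median(dpt$d[res$partition$labels == g]), numeric(1))
  path <- order(med_d)
  tr <- trace_path(res$paga, path, res$partition, dpt, ds$expr,
                   genes = c("gene_001", "gene_002"))
  expect_equal(nrow(tr), res$graph$n_cells)
  expect_true(all(c("gene_001", "gene_001_smooth") %in% names(tr)))
  # within each group the distances are sorted
  for (g in path) {
    dd <- tr$d[tr$group == res$partition$group_names[g]]
    expect_true(all(diff(dd) >= 0))
  }
  # the trace follows the true time closely on a linear trajectory
  truth_t <- ds$true_time[match(tr$cell_id, rownames(ds$expr))]
  expect_gt(cor(seq_len(nrow(tr)), truth_t, method = "spearman"), 0.9)

  # single-group path reduces to a plain sort by d
  tr1 <- trace_path(res$paga, path[1], res$partition, dpt, ds$expr,
                    genes = "gene_001")
  expect_true(all(diff(tr1$d) >= 0))
})

test_that("paths through disconnected groups are rejected", {
  set.seed(56)
  ds <- simulate_tree(linear_topology(1), cells_per_segment = 80, seed = 3)
  ds <- add_disconnected_cluster(ds, n_cells = 40, seed = 3)
  g <- build_knn_graph(unclass(ds$expr), k = 8)
  part <- partitioning(ds$true_branch)
  pg <- threshold_graph(
    connectivity_undirected(count_inter_edges(g, part), part, k = 8), 0)
  tm <- transition_matrix(g)
  root <- which.min(ds$true_time)
  dpt <- suppressMessages(dpt_distance(tm, root))
  expect_error(trace_path(pg, c(1, 2), part, dpt, ds$expr, "gene_001"),
               "not connected|disconnected")
})

test_that("DPT results serialize infinities explicitly", {
  g <- neighbor_graph(4, data.frame(i = c(1, 3), j = c(2, 4)))
  tm <- transition_matrix(g)
  d <- dpt_distance(tm, 1, n_comps = Inf)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dpt(d, f)
  back <- read.csv(f, stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "character"))
  expect_equal(back$d[3:4], c("inf", "inf"))
  expect_equal(as.numeric(back$d[1]), 0)
})
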