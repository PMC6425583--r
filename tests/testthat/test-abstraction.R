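complete_graph <- function(n) {
  p <- t(combn(n, 2))
  neighbor_graph(n, data.frame(i = p[, 1], j = p[, 2]))
}

test_that("inter-edge counting matches exhaustive enumeration", {
  # K4 split 2|2: 4 of the 6 edges cross
  g <- complete_graph(4)
  p <- partitioning(c(1, 1, 2, 2))
  ct <- count_inter_edges(g, p)
  expect_equal(ct$e[1, 2], 4)
  expect_equal(ct$e, t(ct$e))
  expect_equal(diag(ct$e), c(0, 0))
  expect_equal(ct$degree, c(6, 6))  # each group: 1 intra (x2) + 4 inter

  # two disjoint cliques as two groups: no inter-edges
  p2 <- t(combn(3, 2))
  g2 <- neighbor_graph(6, data.frame(i = c(p2[, 1], p2[, 1] + 3),
                                     j = c(p2[, 2], p2[, 2] + 3)))
  ct2 <- count_inter_edges(g2, partitioning(rep(1:2, each = 3)))
  expect_equal(ct2$e[1, 2], 0)

  # single group: 1x1 zero matrix
  ct3 <- count_inter_edges(g, partitioning(rep(1, 4)))
  expect_equal(ct3$e, matrix(0, 1, 1))
})

test_that("connectivity evaluates the declared null exactly", {
  # n = 4 connected, k = 1, two groups of 2, one inter-edge:
  # expected = 1 * 2 * 2 / 3, theta = 3/4
  g <- neighbor_graph(4, data.frame(i = c(1, 3, 1), j = c(2, 4, 3)))
  p <- partitioning(c(1, 1, 2, 2))
  pg <- connectivity_undirected(count_inter_edges(g, p), p, k = 1)
  expect_equal(pg$expected[1, 2], 4 / 3)
  expect_equal(pg$theta[1, 2], 3 / 4)

  # zero inter-edges force zero connectivity even with positive expectation
  g0 <- neighbor_graph(4, data.frame(i = c(1, 3), j = c(2, 4)))
  pg0 <- connectivity_undirected(count_inter_edges(g0, p), p, k = 1)
  expect_equal(pg0$theta[1, 2], 0)

  # far-above-expected counts cap at 1
  gK <- complete_graph(8)
  pK <- partitioning(rep(1:2, each = 4))
  pgK <- connectivity_undirected(count_inter_edges(gK, pK), pK, k = 1)
  expect_equal(pgK$theta[1, 2], 1)
  pgK_uncapped <- connectivity_undirected(count_inter_edges(gK, pK), pK,
                                          k = 1, cap = FALSE)
  expect_gt(pgK_uncapped$theta[1, 2], 1)
})

test_that("a degenerate null with observed edges warns and reports 1", {
  g <- neighbor_graph(4, data.frame(i = c(1, 3, 1), j = c(2, 4, 3)))
  p <- partitioning(c(1, 1, 2, 2))
  ct <- count_inter_edges(g, p)
  null_zero <- function(counts, k) matrix(0, 2, 2)
  expect_warning(pg <- connectivity_undirected(ct, p, k = 1, null = null_zero),
                 "zero")
  expect_equal(pg$theta[1, 2], 1)
})

test_that("theta equals the brute-force statistic on random small graphs", {
  for (case_seed in 1:300) {
    cs <- random_graph_case(case_seed)
    g <- neighbor_graph(cs$n, cs$edges)
    p <- partitioning(cs$labels)
    pg <- suppressWarnings(
      connectivity_undirected(count_inter_edges(g, p), p, k = cs$k))
    oracle <- brute_theta(cs$n, cs$edges, cs$labels, cs$k)
    expect_lt(max(abs(pg$theta - oracle)), 1e-12)
  }
})

test_that("relabeling groups permutes the connectivity matrix accordingly", {
  set.seed(41)
  coords <- matrix(rnorm(120 * 2), 120, 2)
  g <- build_knn_graph(coords, k = 5)
  p <- partition_graph(g, seed = 1)
  pg <- connectivity_undirected(count_inter_edges(g, p), p, k = 5)
  perm <- sample(p$n_groups)
  relabeled <- partitioning(perm[p$labels])
  # partitioning() re-encodes by first appearance; build the inverse map
  inv <- match(seq_len(p$n_groups), relabeled$labels[match(seq_len(p$n_groups), p$labels)])
  pg2 <- connectivity_undirected(count_inter_edges(g, relabeled), relabeled,
                                 k = 5)
  code <- relabeled$labels[match(seq_len(p$n_groups), p$labels)]
  expect_equal(pg2$theta[code, code], pg$theta)
})

test_that("theta is monotone non-decreasing in the observed count", {
  g <- neighbor_graph(10, data.frame(i = c(1:4, 6:9), j = c(2:5, 7:10)))
  p <- partitioning(rep(1:2, each = 5))
  ct <- count_inter_edges(g, p)
  thetas <- vapply(1:5, function(e_ij) {
    ct$e[1, 2] <- e_ij; ct$e[2, 1] <- e_ij
    suppressWarnings(connectivity_undirected(ct, p, k = 2))$theta[1, 2]
  }, numeric(1))
  expect_true(all(diff(thetas) >= 0))
})

test_that("a disconnected group leaves the remaining statistics bit-identical", {
  set.seed(42)
  ds <- simulate_tree(y_topology(), cells_per_segment = 120, seed = 9)
  ds2 <- add_disconnected_cluster(ds, n_cells = 60, seed = 9)
  g1 <- build_knn_graph(unclass(ds$expr), k = 10)
  g2 <- build_knn_graph(unclass(ds2$expr), k = 10)
  p1 <- partition_graph(g1, seed = 9)
  G <- p1$n_groups
  p2 <- partitioning(c(p1$labels, rep(G + 1, 60)))
  th1 <- connectivity_undirected(count_inter_edges(g1, p1), p1, k = 10)
  th2 <- connectivity_undirected(count_inter_edges(g2, p2), p2, k = 10)
  expect_identical(th2$theta[seq_len(G), seq_len(G)], th1$theta)
  expect_equal(max(th2$theta[G + 1, ]), 0)
})

test_that("directed abstraction computes the net-flow tendency", {
  p <- partitioning(c(1, 1, 2, 2))
  # all arrows group 1 -> group 2
  v1 <- data.frame(source = c(1, 2), target = c(3, 4))
  t1 <- connectivity_directed(v1, p)$tendency
  expect_equal(t1[1, 2], 1)
  expect_equal(t1, -t(t1))
  # balanced arrows cancel
  v2 <- data.frame(source = c(1, 3), target = c(3, 1))
  expect_equal(connectivity_directed(v2, p)$tendency[1, 2], 0)
  # 3 forward, 1 backward: (3 - 1) / 4
  v3 <- data.frame(source = c(1, 1, 2, 3), target = c(3, 4, 3, 2))
  expect_equal(connectivity_directed(v3, p)$tendency[1, 2], 0.5)
  expect_warning(connectivity_directed(v1[0, ], p), "empty")
})

test_that("thresholding keeps exactly the edges at or above the cutoff", {
  g <- complete_graph(6)
  p <- partitioning(c(1, 1, 2, 2, 3, 3))
  pg <- connectivity_undirected(count_inter_edges(g, p), p, k = 2)
  all_kept <- threshold_graph(pg, 0)
  expect_equal(nrow(all_kept$edges_kept), sum(pg$e[upper.tri(pg$e)] > 0))
  top_only <- threshold_graph(pg, 1)
  expect_true(all(top_only$edges_kept$theta == 1))
  # monotone: higher threshold keeps a subset
  mid <- threshold_graph(pg, 0.5)
  key <- function(ed) paste(ed$i, ed$j)
  expect_true(all(key(top_only$edges_kept) %in% key(mid$edges_kept)))
  expect_true(all(key(mid$edges_kept) %in% key(all_kept$edges_kept)))
  expect_error(threshold_graph(pg, 1.5), "parameter error")
})

test_that("the spanning forest picks maximum-confidence trees deterministically", {
  # chain A-B, B-C strong; A-C weak: tree keeps the two strong edges
  pg <- structure(list(
    n_groups = 3,
    theta = matrix(c(0, .9, .2, .9, 0, .8, .2, .8, 0), 3, 3),
    e = matrix(c(0, 5, 1, 5, 0, 4, 1, 4, 0), 3, 3),
    expected = matrix(1, 3, 3), group_sizes = c(2, 2, 2),
    group_names = c("A", "B", "C"), k = 2, threshold = NA_real_,
    edges_kept = NULL, tendency = NULL), class = "PagaGraph")
  tr <- spanning_tree(pg)
  expect_equal(tr$edges[, c("i", "j")], data.frame(i = c(1, 2), j = c(2, 3)),
               ignore_attr = TRUE)

  # equal-weight triangle: 2 edges, lexicographic tie-break picks (1,2), (1,3)
  pg$theta <- matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3, 3)
  pg$e <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
  tr2 <- spanning_tree(pg)
  expect_equal(tr2$edges[, c("i", "j")], data.frame(i = c(1, 1), j = c(2, 3)),
               ignore_attr = TRUE)

  # two disconnected groups: empty forest of two singleton trees
  pg0 <- structure(list(n_groups = 2, theta = matrix(0, 2, 2),
                        e = matrix(0, 2, 2), expected = matrix(0, 2, 2),
                        group_sizes = c(1, 1), group_names = c("A", "B"),
                        k = 1, threshold = NA_real_, edges_kept = NULL,
                        tendency = NULL), class = "PagaGraph")
  expect_equal(nrow(spanning_tree(pg0)$edges), 0)
})

test_that("resolution mapping reports plurality coarse groups with overlap", {
  fine <- partitioning(c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3))
  coarse <- partitioning(c(1, 1, 1, 1, 1, 2, 2, 2, 1, 1))
  m <- map_resolutions(fine, fine)
  expect_equal(m$coarse, m$fine)
  expect_equal(m$overlap, rep(1, 3))
  m2 <- map_resolutions(fine, coarse)
  expect_equal(m2$coarse, c(1, 1, 2))
  expect_equal(m2$overlap[3], 0.6)
})

test_that("PAGA graphs write GraphML, CSV and JSON artifacts", {
  g <- complete_graph(6)
  p <- partitioning(c(1, 1, 2, 2, 3, 3))
  pg <- threshold_graph(
    connectivity_undirected(count_inter_edges(g, p), p, k = 2), 0.01)
  d <- withr::local_tempdir()
  files <- write_paga(pg, file.path(d, "paga"))
  expect_true(all(file.exists(files)))
  gm <- igraph::read_graph(file.path(d, "paga.graphml"), format = "graphml")
  expect_equal(igraph::vcount(gm), 3)
  expect_equal(igraph::ecount(gm), nrow(pg$edges_kept))
  js <- jsonlite::read_json(file.path(d, "paga.json"))
  expect_equal(js$n_groups, 3)
})
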