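toy_paga <- function(theta_edges, n) {
  theta <- matrix(0, n, n)
  e <- matrix(0, n, n)
  for (r in seq_len(nrow(theta_edges))) {
    i <- theta_edges$i[r]; j <- theta_edges$j[r]
    theta[i, j] <- theta[j, i] <- theta_edges$theta[r]
    e[i, j] <- e[j, i] <- 1
  }
  pg <- structure(list(n_groups = n, theta = theta, e = e,
                       expected = matrix(1, n, n), group_sizes = rep(1, n),
                       group_names = as.character(seq_len(n)), k = 1,
                       threshold = NA_real_, edges_kept = NULL,
                       tendency = NULL), class = "PagaGraph")
  threshold_graph(pg, 0.01)
}

test_that("coarse layouts are deterministic and separate disconnected nodes", {
  pg <- toy_paga(data.frame(i = integer(0), j = integer(0),
                            theta = numeric(0)), 2)
  l1 <- layout_paga_graph(pg, seed = 1)
  l2 <- layout_paga_graph(pg, seed = 1)
  expect_identical(l1$positions, l2$positions)
  expect_gt(sum((l1$positions[1, ] - l1$positions[2, ])^2), 0)
})

test_that("a chain layout places the middle node between its ends", {
  pg <- toy_paga(data.frame(i = c(1, 2), j = c(2, 3), theta = c(1, 1)), 3)
  l <- layout_paga_graph(pg, seed = 3, n_iter = 2000)
  p <- l$positions
  # project onto the principal axis of the three points: B strictly between
  ax <- prcomp(p)$x[, 1]
  expect_true(ax[2] > min(ax[c(1, 3)]) && ax[2] < max(ax[c(1, 3)]))
})

test_that("rectangle initialization confines groups to disjoint squares", {
  coarse <- structure(list(positions = matrix(c(0, 0, 2, 0, 0, 3), ncol = 2,
                                              byrow = TRUE,
                                              dimnames = list(c("a", "b", "c"),
                                                              c("x", "y"))),
                           level = "group"), class = "Layout")
  assoc <- rep(1:3, each = 50)
  l <- init_fine_from_coarse(coarse, assoc, seed = 5)
  half <- c(1, 1, 1.5)  # half the distance to each node's nearest neighbor
  for (g in 1:3) {
    pts <- l$positions[assoc == g, ]
    offs <- abs(sweep(pts, 2, coarse$positions[g, ]))
    expect_true(all(offs <= half[g] + 1e-12))
  }
  # determinism
  l2 <- init_fine_from_coarse(coarse, assoc, seed = 5)
  expect_identical(l$positions, l2$positions)
  # two coarse nodes at distance 2: squares of half-edge 0.5... scaled here:
  # no fine point of one group may fall inside another group's rectangle
  for (g in 1:3) for (h in 1:3) {
    if (g == h) next
    pts <- l$positions[assoc == g, ]
    inside <- abs(pts[, 1] - coarse$positions[h, 1]) <= half[h] &
      abs(pts[, 2] - coarse$positions[h, 2]) <= half[h]
    expect_equal(sum(inside), 0)
  }
})

test_that("a single coarse node warns and uses a unit half-edge", {
  coarse <- structure(list(positions = matrix(c(1, 1), 1, 2,
                                              dimnames = list("a", c("x", "y"))),
                           level = "group"), class = "Layout")
  expect_warning(l <- init_fine_from_coarse(coarse, rep(1, 20), seed = 1),
                 "single coarse node")
  expect_true(all(abs(sweep(l$positions, 2, c(1, 1))) <= 1))
})

test_that("coarse positions are coordinate-wise medians of their members", {
  pos <- matrix(c(0, 0, 2, 0, 1, 10, 5, 5), ncol = 2, byrow = TRUE)
  fine <- structure(list(positions = pos, level = "cell"), class = "Layout")
  part <- partitioning(c(1, 1, 1, 2))
  cl <- coarse_from_fine(fine, part)
  expect_equal(unname(cl$positions[1, ]), c(1, 0))
  expect_equal(unname(cl$positions[2, ]), c(5, 5))  # singleton group

  # oracle: sort-based median per coordinate on random layouts
  set.seed(61)
  pos2 <- matrix(rnorm(200), 100, 2)
  part2 <- partitioning(sample(1:5, 100, replace = TRUE))
  cl2 <- coarse_from_fine(structure(list(positions = pos2, level = "cell"),
                                    class = "Layout"), part2)
  for (g in 1:part2$n_groups) {
    rows <- pos2[part2$labels == g, , drop = FALSE]
    med <- c(sort(rows[, 1])[ceiling(nrow(rows) / 2)],
             sort(rows[, 2])[ceiling(nrow(rows) / 2)])
    if (nrow(rows) %% 2 == 1) {
      expect_equal(unname(cl2$positions[g, ]), med)
    }
  }
})

test_that("median of rectangle samples returns near the coarse position", {
  set.seed(62)
  coarse_pos <- matrix(rnorm(10), 5, 2)
  rownames(coarse_pos) <- paste0("g", 1:5)
  colnames(coarse_pos) <- c("x", "y")
  coarse <- structure(list(positions = coarse_pos, level = "group"),
                      class = "Layout")
  assoc <- rep(1:5, each = 80)
  fine <- init_fine_from_coarse(coarse, assoc, seed = 7)
  back <- coarse_from_fine(fine, partitioning(assoc))
  d <- as.matrix(dist(coarse_pos, method = "maximum")); diag(d) <- Inf
  half <- apply(d, 1, min) / 2
  expect_true(all(abs(back$positions - coarse_pos) <= half))
})

test_that("refinement with zero iterations returns the initialization", {
  set.seed(63)
  g <- build_knn_graph(matrix(rnorm(60), 30, 2), k = 4)
  init <- structure(list(positions = matrix(rnorm(60), 30, 2), level = "cell"),
                    class = "Layout")
  out <- embed_cells(g, init, n_iter = 0, seed = 1)
  expect_equal(out$positions, init$positions)
  # determinism of the refined layout
  a <- embed_cells(g, init, n_iter = 20, seed = 9)
  b <- embed_cells(g, init, n_iter = 20, seed = 9)
  expect_identical(a$positions, b$positions)
  u <- embed_cells(g, init, method = "umap_like", n_iter = 5, seed = 9)
  expect_false(identical(u$positions, init$positions))
})

test_that("disconnected components stay separated through refinement", {
  set.seed(64)
  blob1 <- matrix(rnorm(100, 0, 0.3), 50, 2)
  blob2 <- matrix(rnorm(100, 8, 0.3), 50, 2)
  g <- build_knn_graph(rbind(blob1, blob2), k = 5)
  part <- partitioning(rep(1:2, each = 50))
  pg <- threshold_graph(
    connectivity_undirected(count_inter_edges(g, part), part, k = 5), 0)
  coarse <- layout_paga_graph(pg, seed = 2)
  init <- init_fine_from_coarse(coarse, part$labels, seed = 2)
  out <- embed_cells(g, init, n_iter = 50, seed = 2)
  # projections onto the centroid axis must not overlap (a separating
  # axis certifies disjoint convex hulls)
  p1 <- out$positions[1:50, ]; p2 <- out$positions[51:100, ]
  ax <- colMeans(p2) - colMeans(p1)
  ax <- ax / sqrt(sum(ax^2))
  expect_lt(max(p1 %*% ax), min(p2 %*% ax))
})
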