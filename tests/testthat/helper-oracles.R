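# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# exhaustive kNN by full pairwise-distance sort, ties by lowest index
brute_knn <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))
    ord[ord != i][seq_len(k)]
  }, integer(k)))
}

# dispersion ranking oracle: plain loops, quantile bins, z-score within bin
brute_normalized_dispersion <- function(x, n_bins = 20) {
  G <- ncol(x)
  mu <- numeric(G); disp <- numeric(G)
  for (g in seq_len(G)) {
    mu[g] <- mean(x[, g])
    disp[g] <- if (mu[g] > 0) var(x[, g]) / mu[g] else 0
  }
  n_bins <- max(1, min(n_bins, length(unique(mu))))
  brk <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = brk, include.lowest = TRUE)
  out <- numeric(G)
  for (b in levels(bin)) {
    idx <- which(bin == b)
    m <- mean(disp[idx]); s <- sd(disp[idx])
    out[idx] <- if (is.na(s) || s == 0) disp[idx] - m else (disp[idx] - m) / s
  }
  out
}

# connected components by breadth-first search on an edge list
brute_components <- function(n, edges) {
  comp <- rep(0L, n)
  cid <- 0L
  adj <- vector("list", n)
  for (r in seq_len(NROW(edges))) {
    adj[[edges$i[r]]] <- c(adj[[edges$i[r]]], edges$j[r])
    adj[[edges$j[r]]] <- c(adj[[edges$j[r]]], edges$i[r])
  }
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

# brute-force connectivity statistic: count inter-edges by direct loops and
# evaluate the declared component-conditioned null from first principles
brute_theta <- function(n, edges, labels, k) {
  G <- max(labels)
  comp <- brute_components(n, edges)
  e <- matrix(0, G, G)
  for (r in seq_len(NROW(edges))) {
    a <- labels[edges$i[r]]; b <- labels[edges$j[r]]
    if (a != b) { e[a, b] <- e[a, b] + 1; e[b, a] <- e[b, a] + 1 }
  }
  theta <- matrix(0, G, G)
  for (a in seq_len(G)) for (b in seq_len(G)) {
    if (a == b || e[a, b] == 0) next
    eh <- 0
    for (cc in unique(comp)) {
      nc <- sum(comp == cc)
      if (nc < 2) next
      na <- sum(labels == a & comp == cc)
      nb <- sum(labels == b & comp == cc)
      eh <- eh + k * na * nb / (nc - 1)
    }
    theta[a, b] <- if (eh == 0) 1 else min(1, e[a, b] / eh)
  }
  theta
}

# all-pairs shortest paths by Bellman-Ford relaxation
brute_shortest_paths <- function(n, edges, lengths) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (src in seq_len(n)) {
    for (iter in seq_len(n)) {
      changed <- FALSE
      for (r in seq_len(NROW(edges))) {
        i <- edges$i[r]; j <- edges$j[r]; w <- lengths[r]
        if (D[src, i] + w < D[src, j] - 1e-15) { D[src, j] <- D[src, i] + w; changed <- TRUE }
        if (D[src, j] + w < D[src, i] - 1e-15) { D[src, i] <- D[src, j] + w; changed <- TRUE }
      }
      if (!changed) break
    }
  }
  D
}

# random graph + partition generator for the connectivity oracle sweep
random_graph_case <- function(seed) {
  set.seed(seed)
  n <- sample(2:8, 1)
  pairs <- t(combn(n, 2))
  m <- sample.int(nrow(pairs), sample.int(nrow(pairs), 1))
  edges <- data.frame(i = pairs[m, 1], j = pairs[m, 2])
  G <- sample.int(min(3, n), 1)
  labels <- sample.int(G, n, replace = TRUE)
  # dense ids in first-appearance order (the partitioning convention)
  labels <- match(labels, unique(labels))
  list(n = n, edges = edges, labels = labels, k = sample(1:4, 1))
}

# simulated dataset + default pipeline, shared by several tests
run_default_pipeline <- function(topology, seed, cells_per_segment = 200) {
  ds <- simulate_tree(topology, cells_per_segment = cells_per_segment,
                      seed = seed)
  res <- paga_workflow(ds$expr, paga_config(seed = seed))
  truth <- ds$true_topology$edges
  attr(truth, "n_groups") <- ds$true_topology$n_segments
  list(ds = ds, res = res, truth = truth,
       truth_part = partitioning(ds$true_branch, rownames(ds$expr)))
}
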