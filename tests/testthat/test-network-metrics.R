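test_that("normalize_weights scales by the maximum and is idempotent", {
  m <- cm(sym_from_upper(3, c(2, 4, 0)))
  n1 <- normalize_weights(m)
  expect_equal(max(n1$weights), 1)
  expect_equal(sort(unique(as.numeric(n1$weights))), c(0, 0.5, 1))
  expect_equal(normalize_weights(n1)$weights, n1$weights)
  expect_error(normalize_weights(cm(matrix(0, 3, 3))), "all-zero")
})

test_that("proportional_threshold keeps the strongest floor(S*E) edges", {
  m <- cm(sym_from_upper(4, c(6, 5, 4, 3, 2, 1)))
  g <- proportional_threshold(m, 0.5)           # floor(0.5 * 6) = 3 edges
  kept <- sort(g$weights[upper.tri(g$weights)][g$weights[upper.tri(g$weights)] > 0])
  expect_equal(kept, c(4, 5, 6))
  expect_equal(proportional_threshold(m, 1)$weights, m$weights)
  gz <- proportional_threshold(cm(matrix(0, 4, 4)), 0.5)
  expect_equal(sum(gz$weights), 0)
  expect_error(proportional_threshold(m, 0), "S must be")
  expect_error(proportional_threshold(m, 1.2), "S must be")
})

test_that("threshold tie-breaking is deterministic by upper-triangle index", {
  # all six candidate edges weight 1: keep the 3 with smallest (row, col)
  m <- cm(sym_from_upper(4, rep(1, 6)))
  g <- proportional_threshold(m, 0.5)
  ut <- which(upper.tri(g$weights), arr.ind = TRUE)
  kept <- ut[g$weights[ut] > 0, , drop = FALSE]
  ord <- order(kept[, 1], kept[, 2])
  # ascending (row, col): (1,2), (1,3), (1,4) win the three slots
  expect_equal(unname(kept[ord, ]), rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_identical(g$weights, proportional_threshold(m, 0.5)$weights)
})

test_that("shortest_distances matches hand values and handles Inf", {
  two <- cm(sym_from_upper(2, 4))
  expect_equal(shortest_distances(two)[1, 2], 0.25)
  p3 <- cm(sym_from_upper(3, c(1, 0, 1)))       # path 1-2-3
  d <- shortest_distances(p3)
  expect_equal(d[1, 3], 2)
  disc <- cm(sym_from_upper(3, c(1, 0, 0)))     # node 3 isolated
  expect_equal(shortest_distances(disc)[1, 3], Inf)
})

test_that("distances equal the Floyd-Warshall oracle on random graphs", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    W <- rand_graph(n, runif(1, 0.2, 0.8))
    expect_dist_equal(shortest_distances(cm(W)), fw_distances(W))
  }
})

test_that("distances agree with igraph on a weighted toy", {
  set.seed(3)
  W <- rand_graph(10, 0.5)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  D_ig <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  expect_lt(max(abs(shortest_distances(cm(W)) - unname(D_ig))), 1e-10)
})

test_that("characteristic path length and global efficiency on toys", {
  k4 <- cm(sym_from_upper(4, rep(1, 6)))
  d4 <- shortest_distances(k4)
  expect_equal(as.numeric(characteristic_path_length(d4)), 1)
  expect_equal(global_efficiency(d4), 1)
  p3 <- cm(sym_from_upper(3, c(1, 0, 1)))
  d3 <- shortest_distances(p3)
  expect_equal(as.numeric(characteristic_path_length(d3)), 4 / 3)
  expect_equal(global_efficiency(d3), (1 + 1 + 0.5) / 3)
  empty <- shortest_distances(cm(matrix(0, 3, 3)))
  cpl <- characteristic_path_length(empty)
  expect_equal(as.numeric(cpl), Inf)
  expect_equal(attr(cpl, "n_infinite_pairs"), 6)
  expect_equal(global_efficiency(empty), 0)
  expect_error(characteristic_path_length(matrix(0, 1, 1)), "2 nodes")
})

test_that("Onnela clustering matches hand computations", {
  tri <- cm(sym_from_upper(3, c(1, 1, 1)))
  wc <- weighted_clustering(proportional_threshold(tri, 1))
  expect_equal(unname(wc$per_node), rep(1, 3))
  expect_equal(wc$mean, 1)
  p3 <- cm(sym_from_upper(3, c(1, 0, 1)))
  expect_equal(weighted_clustering(p3)$mean, 0)
  # triangle with weights (1, 1, 0.125): C = (1 * 1 * 0.125)^(1/3) = 0.5
  tw <- cm(sym_from_upper(3, c(1, 1, 0.125)))
  expect_equal(unname(weighted_clustering(tw)$per_node), rep(0.5, 3))
})

test_that("local efficiency reduces to subgraph global efficiency", {
  star <- cm(sym_from_upper(5, c(1, 1, 0, 1, 0, 0, 1, 0, 0, 0)))
  expect_equal(local_efficiency(star, 1), 0)
  k4 <- cm(sym_from_upper(4, rep(1, 6)))
  expect_equal(local_efficiency(k4, 2), 1)
  # node 1 adjacent to 2,3,4; neighbours form the path 2-3-4
  W <- matrix(0, 4, 4)
  W[1, 2:4] <- W[2:4, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1; W[3, 4] <- W[4, 3] <- 1
  expect_equal(local_efficiency(cm(W), 1), (1 + 1 + 0.5) / 3)
  expect_equal(local_efficiency(cm(W), "n01"), (1 + 1 + 0.5) / 3)
  expect_error(local_efficiency(cm(W), 9), "out of range")
})

test_that("trapezoidal AUC handles constants, ramps and gaps", {
  auc <- connectopath:::auc_trapezoid
  th <- default_thresholds()
  expect_length(th, 26)
  expect_equal(as.numeric(auc(th, rep(0.5, 26))), 0.5 * 0.25)
  ramp <- seq(0, 1, length.out = 26)
  expect_equal(as.numeric(auc(th, ramp)), 0.5 * 0.25)
  # infinite values excluded segment-wise
  v <- rep(1, 26); v[1:3] <- Inf
  expect_equal(as.numeric(auc(th, v)), 0.25 - 3 * 0.01)
  expect_length(default_thresholds(inclusive = FALSE), 24)
})

test_that("sweep_metrics equals the composed R-level operations", {
  set.seed(21)
  m <- cm(rand_graph(12, 0.6))
  th <- c(0.1, 0.2, 0.3, 0.4)
  sw <- sweep_metrics(m, th)
  mn <- normalize_weights(m)
  for (t in seq_along(th)) {
    g <- proportional_threshold(mn, th[t])
    d <- shortest_distances(g)
    expect_equal(sw$global_efficiency$values[t], global_efficiency(d))
    expect_equal(sw$char_path_length$values[t],
                 as.numeric(characteristic_path_length(d)))
    expect_equal(sw$mean_clustering$values[t], weighted_clustering(g)$mean)
    for (i in c(1, 5, 12))
      expect_equal(unname(sw$local_efficiency$values[i, t]),
                   local_efficiency(g, i))
  }
  expect_error(sweep_metrics(m, 0.2), "2 thresholds")
  expect_error(sweep_metrics(m, c(0.3, 0.2)), "increasing")
})

test_that("global efficiency is monotone in sparsity (nested graphs)", {
  set.seed(31)
  for (rep in 1:10) {
    m <- normalize_weights(cm(rand_graph(15, 0.7)))
    ge <- vapply(seq(0.1, 0.9, by = 0.1), function(S)
      global_efficiency(shortest_distances(proportional_threshold(m, S))),
      numeric(1))
    expect_true(all(diff(ge) >= -1e-12))
  }
})

test_that("metrics are permutation-equivariant and bounded", {
  set.seed(41)
  m <- normalize_weights(cm(rand_graph(10, 0.6)))
  perm <- sample(10)
  mp <- cm(m$weights[perm, perm])
  g <- proportional_threshold(m, 0.4)
  gp <- proportional_threshold(mp, 0.4)
  d <- shortest_distances(g); dp <- shortest_distances(gp)
  expect_equal(unname(dp), unname(d[perm, perm]))
  expect_equal(global_efficiency(dp), global_efficiency(d))
  expect_equal(unname(weighted_clustering(gp)$per_node),
               unname(weighted_clustering(g)$per_node[perm]))
  for (i in 1:10)
    expect_equal(local_efficiency(gp, i), local_efficiency(g, perm[i]))
  # bounds with max-normalized weights
  expect_true(global_efficiency(d) >= 0 && global_efficiency(d) <= 1)
  expect_true(all(weighted_clustering(g)$per_node >= 0 &
                    weighted_clustering(g)$per_node <= 1))
  leffs <- vapply(1:10, function(i) local_efficiency(g, i), numeric(1))
  expect_true(all(leffs >= 0 & leffs <= 1))
})

test_that("weighted metrics reduce to binary definitions on 0/1 matrices", {
  set.seed(51)
  for (rep in 1:5) {
    W <- sym_from_upper(9, as.numeric(runif(36) < 0.5))
    m <- cm(W)
    d <- shortest_distances(m)
    # binary distances are hop counts
    expect_dist_equal(d, shortest_distances(cm((W > 0) * 1)))
    # binary clustering: 2 * triangles / (k (k - 1))
    A <- (W > 0) * 1
    tri <- diag(A %*% A %*% A)
    k <- rowSums(A)
    cb <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
    expect_equal(unname(weighted_clustering(m)$per_node), unname(cb))
  }
})

test_that("hop-count path length option gives binary CPL", {
  set.seed(61)
  W <- rand_graph(10, 0.6) + sym_from_upper(10, rep(0.01, 45))  # connected
  m <- cm(W)
  th <- c(0.4, 0.6, 0.8)
  sw_h <- sweep_metrics(m, th, path_length = "hops")
  mn <- normalize_weights(m)
  for (t in seq_along(th)) {
    g <- proportional_threshold(mn, th[t])
    dh <- shortest_distances(cm((g$weights > 0) * 1))
    expect_equal(sw_h$char_path_length$values[t],
                 as.numeric(characteristic_path_length(dh)))
  }
})
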