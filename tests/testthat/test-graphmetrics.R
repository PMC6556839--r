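test_that("build_network symmetrises counts and carries FA weights", {
  counts <- matrix(c(0, 4, 2, 0), 2, 2, byrow = TRUE)
  fa <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  net <- build_network(counts, fa)
  expect_equal(net$weights[1, 2], 0.5)
  expect_equal(net$weights, t(net$weights))

  # isolated node: zero row/column stays degree 0
  counts3 <- matrix(0, 3, 3)
  counts3[1, 2] <- counts3[2, 1] <- 5
  fa3 <- matrix(0.4, 3, 3); diag(fa3) <- 0
  net3 <- build_network(counts3, fa3)
  expect_equal(sum(net3$weights[3, ]), 0)

  # 4-node path with distinct FA weights, hand-checkable
  counts4 <- matrix(0, 4, 4)
  counts4[1, 2] <- counts4[2, 3] <- counts4[3, 4] <- 10
  fa4 <- matrix(0, 4, 4)
  fa4[1, 2] <- fa4[2, 1] <- 0.4
  fa4[2, 3] <- fa4[3, 2] <- 0.5
  fa4[3, 4] <- fa4[4, 3] <- 0.6
  net4 <- build_network(counts4, fa4)
  expect_equal(net4$weights[1, 2], 0.4)
  expect_equal(net4$weights[2, 3], 0.5)
  expect_equal(net4$weights[3, 4], 0.6)
  expect_equal(sum(net4$weights > 0), 6)  # 3 undirected edges

  expect_error(build_network(matrix(0, 2, 2), matrix(0, 3, 3)), "fa_matrix")
  expect_error(build_network(counts, matrix(c(0, 1.5, 1.5, 0), 2, 2)), "\\[0,1\\]")
})

test_that("proportional threshold keeps the k largest edges and never invents any", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  w <- w + t(w)
  net <- weighted_network(w)
  thr <- proportional_threshold(net, 0.5)  # keep round(0.5*6) = 3 edges
  kept <- sort(thr$weights[upper.tri(thr$weights)][thr$weights[upper.tri(thr$weights)] > 0])
  expect_equal(kept, c(0.4, 0.5, 0.6))

  expect_equal(proportional_threshold(net, 1)$weights, net$weights)

  sparse <- matrix(0, 4, 4)
  sparse[1, 2] <- sparse[2, 1] <- 0.3
  sparse[3, 4] <- sparse[4, 3] <- 0.7
  thr2 <- proportional_threshold(weighted_network(sparse), 0.5)
  expect_equal(sum(thr2$weights > 0) / 2, 2)  # both kept, none invented

  expect_error(proportional_threshold(net, 0), "density")
  expect_error(proportional_threshold(net, 1.2), "density")
})

test_that("threshold ties are broken reproducibly", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  w <- w + t(w)
  net <- weighted_network(w)
  t1 <- proportional_threshold(net, 0.5)
  t2 <- proportional_threshold(net, 0.5)
  expect_identical(t1$weights, t2$weights)
  expect_equal(sum(t1$weights > 0) / 2, 3)
})

test_that("shortest weighted paths match hand enumeration", {
  # 3-node path, unit weights: d13 = 1 + 1
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  D <- shortest_weighted_paths(weighted_network(w))
  expect_equal(D[1, 3], 2)
  expect_equal(diag(D), setNames(rep(0, 3), rownames(D)), ignore_attr = TRUE)

  # triangle: strong relay ties the weak direct edge
  w2 <- matrix(0, 3, 3)
  w2[1, 2] <- w2[2, 1] <- 2; w2[2, 3] <- w2[3, 2] <- 2; w2[1, 3] <- w2[3, 1] <- 1
  D2 <- shortest_weighted_paths(weighted_network(w2))
  expect_equal(D2[1, 3], 1)  # direct 1/1 ties relay 1/2 + 1/2

  # disconnected pair is infinite and contributes zero efficiency
  w3 <- matrix(0, 3, 3)
  w3[1, 2] <- w3[2, 1] <- 1
  D3 <- shortest_weighted_paths(weighted_network(w3))
  expect_equal(D3[1, 3], Inf)
  expect_equal(global_efficiency(weighted_network(w3))$E_j[[3]], 0)
})

test_that("global efficiency reproduces closed-form values", {
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  expect_equal(global_efficiency(weighted_network(k3))$E_G, 1)

  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  e <- global_efficiency(weighted_network(w))
  expect_equal(unname(e$E_j), c(0.75, 1, 0.75))
  expect_equal(e$E_G, 5 / 6)

  expect_equal(global_efficiency(weighted_network(matrix(0, 4, 4)))$E_G, 0)
  expect_error(global_efficiency(weighted_network(matrix(0, 1, 1))), "2 nodes")
})

test_that("efficiency AUC is the trapezoidal integral over density", {
  d <- seq(0.3, 0.9, by = 0.1)
  expect_equal(efficiency_auc(d, rep(0.5, length(d))), 0.3)       # rectangle
  expect_equal(efficiency_auc(c(0.3, 0.9), c(0, 1)), 0.3)          # triangle
  expect_equal(efficiency_auc(c(0.3, 0.6, 0.9), c(0.2, 0.4, 0.8)), 0.27)
  expect_error(efficiency_auc(0.5, 1), "2 densities")
  expect_error(efficiency_auc(c(0.5, 0.4), c(1, 1)), "increasing")
})

test_that("Dijkstra agrees with an independent Floyd-Warshall oracle", {
  for (i in 1:30) {
    net <- random_network(sample(4:10, 1), density = runif(1, 0.3, 0.9), seed = 100 + i)
    D <- shortest_weighted_paths(net)
    expect_lt(max(abs(D - floyd_warshall(inverse_lengths(net))),
                  na.rm = TRUE), 1e-12)
  }
})

test_that("E_G scales linearly in the weights under the inverse map", {
  net <- random_network(12, 0.5, seed = 42)
  e1 <- global_efficiency(net)$E_G
  for (c in c(0.25, 2, 7.5)) {
    scaled <- weighted_network(net$weights * c)
    expect_equal(global_efficiency(scaled)$E_G, c * e1, tolerance = 1e-12)
  }
})

test_that("E_G is non-decreasing in density and equals the mean of E_j", {
  for (i in 1:10) {
    net <- random_network(15, 0.95, seed = 200 + i)
    prof <- efficiency_profile(net, densities = seq(0.2, 1, by = 0.1))
    expect_true(all(diff(prof$E_G) >= -1e-12))
    expect_equal(prof$E_G, unname(colMeans(prof$E_j)))
    expect_equal(prof$auc_global, mean(prof$auc_nodal))
  }
})

test_that("efficiency is invariant to node relabelling", {
  net <- random_network(10, 0.6, seed = 7)
  set.seed(8)
  perm <- sample(10)
  permuted <- weighted_network(net$weights[perm, perm])
  e0 <- global_efficiency(net)
  e1 <- global_efficiency(permuted)
  expect_equal(e1$E_G, e0$E_G)
  expect_equal(sort(unname(e1$E_j)), sort(unname(e0$E_j)))
})

test_that("the neglog length map is accepted and changes distances as expected", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5; w[2, 3] <- w[3, 2] <- 0.5
  D <- shortest_weighted_paths(weighted_network(w), length_map = "neglog")
  expect_equal(D[1, 3], -2 * log(0.5))
})
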