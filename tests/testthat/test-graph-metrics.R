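uniform_complete <- function(n, w = 1) {
  m <- matrix(w, n, n, dimnames = list(sprintf("n%02d", 1:n),
                                       sprintf("n%02d", 1:n)))
  diag(m) <- 0
  m
}

star_graph <- function(n, w = 1) {
  m <- matrix(0, n, n, dimnames = list(sprintf("n%02d", 1:n),
                                       sprintf("n%02d", 1:n)))
  m[1, 2:n] <- w
  m[2:n, 1] <- w
  m
}

test_that("total-strength normalization rescales to unit strength and is idempotent", {
  w <- uniform_complete(4, 2)  # upper-triangle sum = 12
  wn <- normalize_total_strength(w)
  expect_equal(sum(wn[upper.tri(wn)]), 1)
  expect_equal(wn, w / 12)
  expect_equal(normalize_total_strength(wn), wn)
  single <- matrix(c(0, 7, 7, 0), 2, 2,
                   dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(normalize_total_strength(single)["a", "b"], 1)
  expect_error(normalize_total_strength(uniform_complete(3, 0)), "positive")
})

test_that("sparsity thresholding keeps exactly ceiling(s * n(n-1)/2) edges", {
  set.seed(77)
  w <- random_network(10, p_edge = 1)   # all 45 weights positive, distinct
  for (s in seq(0.05, 0.5, by = 0.05)) {
    wt <- threshold_by_sparsity(w, s)
    expect_equal(sum(wt[upper.tri(wt)] > 0), ceiling(s * 45))
    # retained edges are the strongest ones, weights kept not binarized
    kept <- wt[upper.tri(wt)][wt[upper.tri(wt)] > 0]
    dropped <- w[upper.tri(w)][wt[upper.tri(wt)] == 0]
    expect_true(min(kept) >= max(dropped))
    expect_true(all(kept %in% w[upper.tri(w)]))
  }
  expect_equal(threshold_by_sparsity(w, 1), w)
  expect_error(threshold_by_sparsity(w, 0), "sparsity")
  expect_error(threshold_by_sparsity(w, 1.1), "sparsity")
})

test_that("ties at the sparsity cut break deterministically by label pair", {
  w <- uniform_complete(10, 0.5)
  wt <- threshold_by_sparsity(w, 0.5)
  expect_equal(sum(wt[upper.tri(wt)] > 0), ceiling(0.5 * 45))  # 23
  expect_identical(wt, threshold_by_sparsity(w, 0.5))
  # lexicographically earliest pairs kept
  expect_equal(wt["n01", "n02"], 0.5)
})

test_that("closed-form limits hold for complete, star, and path graphs", {
  for (w in c(1, 0.3)) {
    g <- uniform_complete(6, w)
    expect_equal(unname(nodal_clustering(g)), rep(1, 6))
    expect_equal(unname(nodal_degree_centrality(g)), rep(5 * w, 6))
    expect_equal(unname(nodal_efficiency(g)), rep(w, 6))
  }
  st <- star_graph(5)
  expect_equal(unname(nodal_clustering(st))[1], 0)
  expect_equal(unname(nodal_local_efficiency(st))[1], 0)
  expect_equal(unname(nodal_clustering(st))[2], 0)   # degree-1 leaf
  # 3-node path, unit weights: end-node efficiency (1 + 1/2) / 2
  pth <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  pth["a", "b"] <- pth["b", "a"] <- 1
  pth["b", "c"] <- pth["c", "b"] <- 1
  expect_equal(unname(nodal_efficiency(pth))[1], 0.75)
  # uniform triangle: neighbor subgraph of each node is one unit edge
  tri <- uniform_complete(3, 1)
  expect_equal(unname(nodal_local_efficiency(tri)), rep(1, 3))
  # isolated node
  iso <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  iso["a", "b"] <- iso["b", "a"] <- 2
  expect_equal(unname(nodal_degree_centrality(iso))[3], 0)
  expect_equal(unname(nodal_efficiency(iso))[3], 0)
  expect_equal(unname(nodal_local_efficiency(iso))[3], 0)
})

test_that("all four metrics match the brute-force oracles on random networks", {
  set.seed(123)
  for (i in 1:30) {
    w <- random_network(8, p_edge = runif(1, 0.3, 0.9))
    if (all(w == 0)) next
    expect_equal(unname(nodal_degree_centrality(w)), unname(rowSums(w)),
                 tolerance = 1e-10)
    expect_equal(unname(nodal_clustering(w)), oracle_clustering(w),
                 tolerance = 1e-10)
    expect_equal(unname(nodal_efficiency(w)), oracle_nodal_efficiency(w),
                 tolerance = 1e-10)
    expect_equal(unname(nodal_local_efficiency(w)),
                 oracle_local_efficiency(w), tolerance = 1e-10)
  }
})

test_that("metrics scale as expected under uniform weight rescaling", {
  set.seed(321)
  w <- random_network(8, p_edge = 0.7)
  f <- 3.7
  expect_equal(nodal_degree_centrality(w * f),
               nodal_degree_centrality(w) * f)
  expect_equal(nodal_efficiency(w * f), nodal_efficiency(w) * f)
  expect_equal(nodal_clustering(w * f), nodal_clustering(w))  # max-normalized
  # label permutation equivariance
  perm <- sample(8)
  wp <- w[perm, perm]
  expect_equal(nodal_efficiency(wp), nodal_efficiency(w)[perm])
  expect_equal(nodal_clustering(wp), nodal_clustering(w)[perm])
  expect_equal(nodal_local_efficiency(wp), nodal_local_efficiency(w)[perm])
})

test_that("AUC is the trapezoid over the sparsity sweep", {
  s <- seq(0.05, 0.5, by = 0.05)
  expect_equal(metric_auc(rep(3, 10)), 0.45 * 3)
  expect_equal(metric_auc(rep(0, 10)), 0)
  expect_equal(metric_auc(s), 0.45 * 0.275)  # trapezoid of the line v = s
  expect_error(metric_auc(rep(1, 9)), "one value per")
  expect_error(metric_auc(c(rep(1, 9), NA)), "missing")
})

test_that("nodal metric table covers nodes x sparsities x metrics with AUCs", {
  set.seed(55)
  w <- random_network(10, p_edge = 0.9)
  res <- nodal_metric_table(w)
  expect_equal(nrow(res$per_sparsity), 10 * 10 * 4)
  expect_equal(nrow(res$auc), 10 * 4)
  expect_true(all(res$per_sparsity$value >= 0))
  # AUC consistent with the per-sparsity values
  one <- subset(res$per_sparsity, node == "n03" & metric == "Eg")
  one <- one[order(one$sparsity), ]
  expect_equal(res$auc$auc[res$auc$node == "n03" & res$auc$metric == "Eg"],
               metric_auc(one$value))
})

test_that("tool-use subnetwork extraction keeps the canonical 10 nodes", {
  labels <- c(tool_use_nodes(), "extra1", "extra2")
  w <- matrix(runif(144), 12, 12, dimnames = list(labels, labels))
  w <- (w + t(w)) / 2
  diag(w) <- 0
  tu <- tool_use_subnetwork(w)
  expect_equal(rownames(tu), tool_use_nodes())
  expect_error(tool_use_subnetwork(w[1:5, 1:5]), "missing")
})
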