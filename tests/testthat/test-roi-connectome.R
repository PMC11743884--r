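make_counts <- function(vals, labels) {
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  m[upper.tri(m)] <- vals
  m + t(m)
}

test_that("node-size normalization uses the inverse mean-volume convention", {
  labels <- c("a", "b", "c")
  m <- make_counts(c(10, 0, 6), labels)
  v <- c(a = 2, b = 3, c = 1)
  w <- normalize_by_node_size(m, v)
  expect_equal(w["a", "b"], 10 * 2 / 5)   # c = 10, Va = 2, Vb = 3 -> 4
  expect_equal(w["a", "c"], 0)
  expect_true(isSymmetric(w))
  expect_equal(diag(w), setNames(rep(0, 3), labels))

  v_eq <- c(a = 4, b = 4, c = 4)
  expect_equal(normalize_by_node_size(m, v_eq), m / 4)
  expect_error(normalize_by_node_size(m, c(a = 0, b = 1, c = 1)), "positive")
  expect_error(normalize_by_node_size(m[, c(2, 1, 3)], v), "symmetric")
})

test_that("group averaging is the entrywise mean and demands aligned labels", {
  labels <- c("a", "b", "c")
  m1 <- make_counts(c(2, 2, 2), labels)
  m2 <- make_counts(c(4, 4, 4), labels)
  expect_equal(group_average_connectome(list(m1, m2)),
               make_counts(c(3, 3, 3), labels))
  expect_equal(group_average_connectome(list(m1)), m1)
  m3 <- m2[c(2, 1, 3), c(2, 1, 3)]
  expect_error(group_average_connectome(list(m1, m3)), "labels")
})

test_that("normalization commutes with group averaging under shared volumes", {
  set.seed(8)
  labels <- sprintf("r%d", 1:6)
  v <- setNames(runif(6, 50, 150), labels)
  stack <- lapply(1:4, function(i) make_counts(runif(15, 0, 20), labels))
  a <- group_average_connectome(lapply(stack, normalize_by_node_size, v))
  b <- normalize_by_node_size(group_average_connectome(stack), v)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("top-fraction union ranks, keeps the ceiling count, and unions", {
  labels <- c(mt_seeds(), sprintf("t%d", 1:6))
  g <- matrix(0, 9, 9, dimnames = list(labels, labels))
  # disjoint seed preferences over 6 targets
  g["MST", c("t1", "t2", "t3", "t4", "t5", "t6")] <- c(9, 8, 7, 1, 2, 3)
  g["MT",  c("t1", "t2", "t3", "t4", "t5", "t6")] <- c(1, 2, 3, 9, 8, 7)
  g["FST", c("t1", "t2", "t3", "t4", "t5", "t6")] <- c(7, 1, 2, 3, 9, 8)
  g <- pmax(g, t(g))

  expect_setequal(top_fraction_union(g, fraction = 1),
                  sprintf("t%d", 1:6))
  u <- top_fraction_union(g, fraction = 0.5)
  # per-seed top-3 lists: {t1,t2,t3}, {t4,t5,t6}, {t5,t6,t1}
  expect_setequal(u, sprintf("t%d", 1:6))
  u2 <- top_fraction_union(g, fraction = 1 / 6)
  expect_setequal(u2, c("t1", "t4", "t5"))
  expect_error(top_fraction_union(g, fraction = 0), "fraction")
})

test_that("top-fraction union is monotone in the fraction", {
  set.seed(14)
  labels <- c(mt_seeds(), sprintf("t%02d", 1:20))
  g <- make_counts(runif(choose(23, 2), 0, 5), labels)
  sweep <- seq(0.2, 1, by = 0.1)
  unions <- lapply(sweep, function(f) top_fraction_union(g, fraction = f))
  for (k in seq_len(length(sweep) - 1)) {
    expect_true(all(unions[[k]] %in% unions[[k + 1]]))
  }
})

test_that("identical rankings across seeds collapse the union to one list", {
  labels <- c(mt_seeds(), sprintf("t%d", 1:8))
  g <- matrix(0, 11, 11, dimnames = list(labels, labels))
  for (s in mt_seeds()) g[s, sprintf("t%d", 1:8)] <- 8:1
  g <- pmax(g, t(g))
  expect_length(top_fraction_union(g, fraction = 0.5), ceiling(0.5 * 8))
})

test_that("seed-pattern correlation handles identity, reversal, and the Bonferroni cap", {
  v <- setNames(c(5, 3, 8, 1, 9, 2), sprintf("t%d", 1:6))
  expect_equal(seed_pattern_correlation(v, v)$rho, 1)
  rev_ranks <- setNames(-v, names(v))
  expect_equal(seed_pattern_correlation(v, rev_ranks)$rho, -1)
  set.seed(1)
  a <- setNames(runif(10), sprintf("t%d", 1:10))
  b <- setNames(runif(10), sprintf("t%d", 1:10))
  r <- seed_pattern_correlation(a, b, n_tests = 6)
  expect_lte(r$p_adjusted, 1)
  expect_equal(r$p_adjusted, min(1, r$p_value * 6))
  expect_error(seed_pattern_correlation(a[1:2], b[1:2]), "3 targets")
  expect_error(seed_pattern_correlation(a, b[c(2, 1, 3:10)]), "aligned")
})

test_that("Fisher z matches arctanh and clips perfect correlations", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  expect_true(is.finite(fisher_z(1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(-1), -atanh(1 - 1e-7))
  expect_error(fisher_z(1.2), "exceed")
})

test_that("similarity sets have n(n-1)/2 elements and match a brute-force rank oracle", {
  va <- rbind(c(5, 1, 4, 2, 3),
              c(1, 2, 3, 4, 5),
              c(2, 2, 5, 1, 4))
  vb <- rbind(c(3, 4, 1, 5, 2),
              c(5, 4, 3, 2, 1),
              c(1, 3, 3, 2, 5))
  colnames(va) <- colnames(vb) <- sprintf("t%d", 1:5)
  ss <- similarity_sets(va, vb)
  expect_length(ss$set_AA, 3)
  expect_length(ss$set_AB, 3)

  sp <- function(x, y) cor(rank(x), rank(y))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  exp_aa <- vapply(pairs, function(p) sp(va[p[1], ], va[p[2], ]), numeric(1))
  exp_ab <- vapply(pairs, function(p) {
    (sp(va[p[1], ], vb[p[2], ]) + sp(vb[p[1], ], va[p[2], ])) / 2
  }, numeric(1))
  expect_equal(ss$set_AA, exp_aa)
  expect_equal(ss$set_AB, exp_ab)
  expect_equal(ss$z_AB, fisher_z(exp_ab))
})

test_that("two subjects give singleton sets; a shared vector gives rho 1 within", {
  va <- rbind(c(1, 5, 2, 4, 3), c(1, 5, 2, 4, 3))
  vb <- rbind(c(2, 1, 4, 3, 5), c(5, 1, 3, 2, 4))
  colnames(va) <- colnames(vb) <- sprintf("t%d", 1:5)
  ss <- similarity_sets(va, vb)
  expect_length(ss$set_AA, 1)
  expect_equal(ss$set_AA, 1)
  expect_error(similarity_sets(va[1, , drop = FALSE], vb[1, , drop = FALSE]),
               "2 subjects")
  vb2 <- vb
  colnames(vb2) <- sprintf("u%d", 1:5)
  expect_error(similarity_sets(va, vb2), "aligned")
})

test_that("set_AB is symmetric in its two seeds", {
  set.seed(31)
  va <- matrix(runif(40), 4, 10)
  vb <- matrix(runif(40), 4, 10)
  colnames(va) <- colnames(vb) <- sprintf("t%d", 1:10)
  expect_equal(similarity_sets(va, vb)$set_AB,
               similarity_sets(vb, va)$set_AB)
  # Set_{A-A} is Set_{A-B} with B = A
  expect_equal(similarity_sets(va, va)$set_AB,
               similarity_sets(va, va)$set_AA)
})

test_that("similarity table covers all six pair types with correct row counts", {
  set.seed(61)
  mats <- lapply(mt_seeds(), function(s) {
    m <- matrix(runif(5 * 8), 5, 8)
    colnames(m) <- sprintf("t%d", 1:8)
    m
  })
  names(mats) <- mt_seeds()
  tab <- similarity_set_table(mats)
  expect_equal(nrow(tab), 6 * choose(5, 2))
  expect_setequal(unique(tab$pair),
                  c("MST-MST", "MT-MT", "FST-FST",
                    "MST-MT", "MST-FST", "MT-FST"))
  expect_equal(sum(tab$type == "within"), 3 * choose(5, 2))
})
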