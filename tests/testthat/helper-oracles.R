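# Independent brute-force oracles used to pin the metric implementations.
# These deliberately share no code with the package internals.

# Dice coefficients by explicit set construction
oracle_dice_pair <- function(set_a, set_b) {
  inter <- sum(set_a %in% set_b)
  2 * inter / (length(set_a) + length(set_b))
}

oracle_dice_third <- function(set_a, set_b, set_c) {
  inter <- sum(set_a %in% set_b & set_a %in% set_c)
  3 * inter / (length(set_a) + length(set_b) + length(set_c))
}

# MPM dominance by direct evaluation of the printed pairwise inequality
oracle_mpm_label <- function(s) {
  if (all(s == 0)) return(0L)           # UNCLASSIFIED
  for (k in 1:3) {
    others <- s[-k]
    if (all(s[k] > others) &&
        all(abs(s[k] - others) > (s[k] + others) / 2)) {
      return(k)                          # dominant seed k
    }
  }
  4L                                     # OVERLAP
}

# All-pairs shortest paths by Floyd-Warshall on lengths 1/w
oracle_shortest <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_nodal_efficiency <- function(w) {
  n <- nrow(w)
  d <- oracle_shortest(w)
  sapply(seq_len(n), function(i) {
    inv <- 1 / d[i, -i]
    sum(inv[is.finite(inv)]) / (n - 1)
  })
}

oracle_global_efficiency <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  d <- oracle_shortest(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(w[nb, nb, drop = FALSE])
  })
}

# Weighted clustering by explicit neighbor-pair enumeration
oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, n))
  wh <- w / mx
  sapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    acc <- 0
    for (j in nb) {
      for (h in nb) {
        if (j != h) acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
      }
    }
    acc / (k * (k - 1))
  })
}

# Random symmetric weighted network with labelled nodes
random_network <- function(n, p_edge = 0.6, max_w = 1) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- ifelse(runif(sum(up)) < p_edge, runif(sum(up), 0.05, max_w), 0)
  w[up] <- vals
  w <- w + t(w)
  dimnames(w) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  w
}

small_profile_config <- function(seed = 42L, ...) {
  synthetic_config(n_subjects = 6L, n_regions = 40L,
                   grid_shape = c(8L, 8L, 9L), rng_seed = seed, ...)
}
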