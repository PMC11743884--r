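#' Normalize a streamline-count matrix by node size
#'
#' Edge weights are corrected for region size in the spirit of connectome
#' construction with inverse-node-volume scaling: the weight between regions
#' a and b is the raw count divided by the mean of the two node volumes,
#' \eqn{w_{ab} = c_{ab} \cdot 2 / (V_a + V_b)}. Any strictly
#' volume-decreasing convention preserves within-seed rankings; this one is
#' pinned for reproducibility.
#'
#' @param raw_counts Square symmetric nonnegative matrix with region labels as
#'   dimnames.
#' @param node_volumes Named positive vector of node volumes (voxel counts or
#'   mm^3), covering all regions.
#' @return Symmetric normalized `matrix` with zero diagonal.
#' @export
normalize_by_node_size <- function(raw_counts, node_volumes) {
  if (!is.matrix(raw_counts) || nrow(raw_counts) != ncol(raw_counts)) {
    stop("raw_counts must be a square matrix")
  }
  if (max(abs(raw_counts - t(raw_counts))) > 1e-8) {
    stop("raw_counts must be symmetric")
  }
  if (any(raw_counts < 0)) stop("raw_counts must be nonnegative")
  labels <- rownames(raw_counts)
  if (is.null(labels)) stop("raw_counts must carry region labels as dimnames")
  if (!all(labels %in% names(node_volumes))) {
    stop("node_volumes must cover every region label")
  }
  v <- node_volumes[labels]
  if (any(v <= 0)) stop("node volumes must be strictly positive")
  w <- raw_counts * 2 / outer(v, v, "+")
  diag(w) <- 0
  dimnames(w) <- dimnames(raw_counts)
  w
}

#' Group-average connectome
#'
#' Entrywise mean of the subjects' connectome matrices; all matrices must
#' share one region labelling (in the same order).
#'
#' @param stack List of labelled symmetric matrices.
#' @return Matrix of the same shape.
#' @export
group_average_connectome <- function(stack) {
  if (length(stack) < 1L) stop("need at least one connectome")
  labels <- rownames(stack[[1L]])
  for (m in stack) {
    if (!identical(rownames(m), labels) || !identical(colnames(m), labels)) {
      stop("connectome region labels must match across subjects")
    }
  }
  Reduce(`+`, stack) / length(stack)
}

#' Union of each seed's most-connected target regions
#'
#' For each MT+ seed, ranks all non-seed regions by group-level connection
#' strength (descending; ties broken by label order for reproducibility),
#' keeps the top `ceiling(fraction * m)` of the m candidates, and returns the
#' union of the three per-seed lists. The union at a smaller fraction is
#' always a subset of the union at a larger one, which is what makes the
#' robustness sweep (e.g. 0.5 down to 0.2) meaningful.
#'
#' @param group Group-average connectome matrix with labels.
#' @param seeds Seed labels (default the three MT+ subregions).
#' @param fraction Fraction in (0, 1\] of top-connected regions kept per seed.
#' @return Character vector of target labels (sorted), the common target set
#'   for all three seed connectivity vectors.
#' @export
top_fraction_union <- function(group, seeds = mt_seeds(), fraction = 0.5) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  labels <- rownames(group)
  if (!all(seeds %in% labels)) stop("seeds missing from connectome labels")
  candidates <- setdiff(labels, seeds)
  m <- length(candidates)
  keep <- ceiling(fraction * m)
  per_seed <- lapply(seeds, function(s) {
    strength <- group[s, candidates]
    ord <- order(-strength, candidates)
    candidates[ord][seq_len(keep)]
  })
  sort(unique(unlist(per_seed)))
}

#' Extract a seed's connectivity vector over a target set
#'
#' @param connectome Labelled connectome matrix.
#' @param seed Seed region label.
#' @param targets Target region labels (must exclude the MT+ seeds).
#' @return Named numeric vector of strengths.
#' @export
seed_vector <- function(connectome, seed, targets) {
  if (any(targets %in% mt_seeds())) {
    stop("targets must exclude the MT+ seed regions")
  }
  if (!seed %in% rownames(connectome)) stop("seed not in connectome")
  if (!all(targets %in% colnames(connectome))) {
    stop("targets missing from connectome")
  }
  connectome[seed, targets]
}

#' Spearman correlation between two seed connectivity patterns
#'
#' Average-rank Spearman correlation between two seeds' connectivity vectors
#' over an identical target list, with Bonferroni adjustment of the p-value
#' (multiplied by `n_tests` and capped at 1).
#'
#' @param v_a,v_b Named strength vectors over identical targets.
#' @param n_tests Number of tests in the Bonferroni family (default 6: three
#'   seed pairs in each of two species).
#' @return List with `rho`, `p_value`, `p_adjusted`, `n_targets`.
#' @export
seed_pattern_correlation <- function(v_a, v_b, n_tests = 6L) {
  if (length(v_a) != length(v_b)) stop("target lists differ in length")
  if (!is.null(names(v_a)) && !is.null(names(v_b)) &&
      !identical(names(v_a), names(v_b))) {
    stop("target lists must be identical and aligned")
  }
  if (length(v_a) < 3L) stop("need at least 3 targets")
  ct <- suppressWarnings(
    cor.test(v_a, v_b, method = "spearman", exact = FALSE)
  )
  list(
    rho = unname(ct$estimate),
    p_value = ct$p.value,
    p_adjusted = min(1, ct$p.value * n_tests),
    n_targets = length(v_a)
  )
}

#' Fisher z transformation of a correlation coefficient
#'
#' `z = arctanh(rho)`, with `rho` clipped to `+/-(1 - 1e-7)` so that
#' degenerate perfect correlations (which arise on synthetic data) map to a
#' large finite value rather than infinity.
#'
#' @param rho Correlation value(s) in \[-1, 1\].
#' @return Transformed value(s).
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE)) stop("|rho| must not exceed 1")
  atanh(pmin(pmax(rho, -(1 - 1e-7)), 1 - 1e-7))
}

#' Within- and between-seed connectivity similarity sets
#'
#' For two seeds A and B with per-subject connectivity vectors over one
#' aligned target list, computes the parcellation-validation sets:
#' \deqn{Set_{A-A} = \{\rho(v_i^A, v_j^A) : 1 \le i < j \le n\}}
#' \deqn{Set_{A-B} = \{(\rho(v_i^A, v_j^B) + \rho(v_i^B, v_j^A))/2 :
#'   1 \le i < j \le n\}}
#' using average-rank Spearman correlations across subjects, plus Fisher
#' z-transformed copies for downstream statistics. Each set has exactly
#' `n(n-1)/2` elements.
#'
#' @param va,vb Numeric matrices, subjects in rows and targets in columns,
#'   with identical column (target) names.
#' @return List of class `similarity_sets` with `set_AA`, `set_BB`, `set_AB`,
#'   their Fisher-z copies `z_AA`, `z_BB`, `z_AB`, and `n`.
#' @export
similarity_sets <- function(va, vb) {
  if (!identical(dim(va), dim(vb))) stop("subject-by-target shapes differ")
  if (!is.null(colnames(va)) && !is.null(colnames(vb)) &&
      !identical(colnames(va), colnames(vb))) {
    stop("target lists must be aligned")
  }
  n <- nrow(va)
  if (n < 2L) stop("need at least 2 subjects")

  ra <- t(apply(va, 1L, rank))  # average ranks within each subject's vector
  rb <- t(apply(vb, 1L, rank))
  caa <- suppressWarnings(cor(t(ra)))
  cbb <- suppressWarnings(cor(t(rb)))
  cab <- suppressWarnings(cor(t(ra), t(rb)))

  up <- upper.tri(caa)
  set_aa <- caa[up]
  set_bb <- cbb[up]
  set_ab <- ((cab + t(cab)) / 2)[up]

  structure(
    list(
      set_AA = set_aa, set_BB = set_bb, set_AB = set_ab,
      z_AA = fisher_z(set_aa), z_BB = fisher_z(set_bb),
      z_AB = fisher_z(set_ab),
      n = n
    ),
    class = "similarity_sets"
  )
}

#' Tidy similarity-set table for all three MT+ seeds
#'
#' Applies [similarity_sets()] to every seed pair and stacks the results into
#' a long table (one row per subject pair and seed pair), the input expected
#' by a one-way repeated-measures analysis of parcellation validity.
#'
#' @param seed_matrices Named list (`MST`, `MT`, `FST`) of subject-by-target
#'   strength matrices with aligned columns.
#' @return data.frame with columns `pair`, `type` (`within`/`between`),
#'   `i`, `j`, `rho`, `z`.
#' @export
similarity_set_table <- function(seed_matrices) {
  seeds <- mt_seeds()
  stopifnot(all(seeds %in% names(seed_matrices)))
  n <- nrow(seed_matrices[[seeds[1L]]])
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)

  out <- list()
  done_within <- character(0)
  for (a in seq_len(2L)) {
    for (b in seq(a + 1L, 3L)) {
      ss <- similarity_sets(seed_matrices[[seeds[a]]],
                            seed_matrices[[seeds[b]]])
      if (!seeds[a] %in% done_within) {
        out[[length(out) + 1L]] <- data.frame(
          pair = paste(seeds[a], seeds[a], sep = "-"), type = "within",
          i = idx[, 1L], j = idx[, 2L], rho = ss$set_AA, z = ss$z_AA)
        done_within <- c(done_within, seeds[a])
      }
      if (!seeds[b] %in% done_within) {
        out[[length(out) + 1L]] <- data.frame(
          pair = paste(seeds[b], seeds[b], sep = "-"), type = "within",
          i = idx[, 1L], j = idx[, 2L], rho = ss$set_BB, z = ss$z_BB)
        done_within <- c(done_within, seeds[b])
      }
      out[[length(out) + 1L]] <- data.frame(
        pair = paste(seeds[a], seeds[b], sep = "-"), type = "between",
        i = idx[, 1L], j = idx[, 2L], rho = ss$set_AB, z = ss$z_AB)
    }
  }
  do.call(rbind, out)
}
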