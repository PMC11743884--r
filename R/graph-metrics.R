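#' Normalize total network strength to 1
#'
#' Divides every weight by the sum of the unique undirected edge weights so
#' that the network's total connection strength is 1, making networks of
#' different species (and streamline budgets) comparable while preserving
#' proportions.
#'
#' @param w Symmetric nonnegative weight matrix with zero diagonal.
#' @return Rescaled weight matrix.
#' @export
normalize_total_strength <- function(w) {
  check_weight_matrix(w)
  total <- sum(w[upper.tri(w)])
  if (total <= 0) stop("network has no positive weight to normalize")
  w / total
}

check_weight_matrix <- function(w) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("weights must be square")
  if (max(abs(w - t(w))) > 1e-10) stop("weights must be symmetric")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (any(diag(w) != 0)) stop("self-loops are not allowed")
  invisible(w)
}

#' Threshold a weighted network at a sparsity level
#'
#' Keeps the `ceiling(s * n(n-1)/2)` strongest undirected edges and zeroes
#' the rest. Weights are kept, not binarized. Ties at the cut are broken
#' deterministically: weight descending, then lexicographic node-label pair.
#'
#' @param w Symmetric weight matrix with node labels.
#' @param s Sparsity fraction in (0, 1\]: the fraction of all possible edges
#'   retained.
#' @return Thresholded weight matrix of the same shape.
#' @export
threshold_by_sparsity <- function(w, s) {
  check_weight_matrix(w)
  if (!is.numeric(s) || length(s) != 1L || s <= 0 || s > 1) {
    stop("sparsity must lie in (0, 1]")
  }
  n <- nrow(w)
  labels <- rownames(w)
  if (is.null(labels)) labels <- sprintf("n%03d", seq_len(n))
  idx <- which(upper.tri(w), arr.ind = TRUE)
  weight <- w[upper.tri(w)]
  keep_k <- ceiling(s * n * (n - 1) / 2)
  ord <- order(-weight, labels[idx[, 1L]], labels[idx[, 2L]])
  keep <- ord[seq_len(keep_k)]

  out <- matrix(0, n, n, dimnames = dimnames(w))
  ka <- idx[keep, 1L]
  kb <- idx[keep, 2L]
  out[cbind(ka, kb)] <- weight[keep]
  out[cbind(kb, ka)] <- weight[keep]
  out
}

graph_from_weights <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

## All-pairs shortest-path lengths on edge lengths 1/w (stronger = closer).
shortest_lengths <- function(w) {
  n <- nrow(w)
  if (n < 2L || all(w == 0)) {
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    return(d)
  }
  g <- graph_from_weights(w)
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

## Global efficiency of a whole weighted network: mean over ordered node
## pairs of 1/d, unreachable pairs contributing 0.
global_efficiency <- function(w) {
  n <- nrow(w)
  if (n < 2L) return(0)
  d <- shortest_lengths(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal degree centrality (strength)
#'
#' Weighted degree centrality of each node: the sum of its incident edge
#' weights (node strength). `weighted = FALSE` gives the binary degree
#' (number of direct connections) instead.
#'
#' @param w (Thresholded) symmetric weight matrix.
#' @param weighted Use weights (default) or binary degree.
#' @return Named vector of Dc values.
#' @export
nodal_degree_centrality <- function(w, weighted = TRUE) {
  check_weight_matrix(w)
  if (weighted) rowSums(w) else rowSums(w > 0)
}

#' Nodal weighted clustering coefficient
#'
#' Geometric-mean triangle form of the weighted clustering coefficient:
#' with weights scaled by the network maximum, \eqn{\hat w = w / \max(w)},
#' \deqn{Cp_i = \frac{\sum_{j \ne h} (\hat w_{ij} \hat w_{ih} \hat
#' w_{jh})^{1/3}}{k_i (k_i - 1)}}
#' where \eqn{k_i} is the binary degree. Nodes with fewer than two neighbors
#' have no possible triangle and get 0.
#'
#' @param w (Thresholded) symmetric weight matrix.
#' @return Named vector of Cp values.
#' @export
nodal_clustering <- function(w) {
  check_weight_matrix(w)
  mx <- max(w)
  if (mx == 0) return(setNames(rep(0, nrow(w)), rownames(w)))
  w3 <- (w / mx)^(1 / 3)
  k <- rowSums(w > 0)
  num <- diag(w3 %*% w3 %*% w3)  # 2 x (geometric-mean triangle intensity)
  cp <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  setNames(cp, rownames(w))
}

#' Nodal (global) efficiency
#'
#' \deqn{Eg_i = \frac{1}{n-1} \sum_{j \ne i} 1 / d_{ij}} with shortest-path
#' lengths computed on edge lengths \eqn{1/w}; unreachable pairs contribute
#' 0, so fragmented thresholded networks stay finite.
#'
#' @param w (Thresholded) symmetric weight matrix.
#' @return Named vector of Eg values.
#' @export
nodal_efficiency <- function(w) {
  check_weight_matrix(w)
  n <- nrow(w)
  d <- shortest_lengths(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  setNames(rowSums(inv) / (n - 1), rownames(w))
}

#' Nodal local efficiency
#'
#' Global efficiency of the subgraph induced by a node's first neighbors with
#' the node itself removed: how efficiently the neighborhood communicates
#' without the node. Nodes with fewer than two neighbors get 0.
#'
#' @param w (Thresholded) symmetric weight matrix.
#' @return Named vector of Eloc values.
#' @export
nodal_local_efficiency <- function(w) {
  check_weight_matrix(w)
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2L) next
    out[i] <- global_efficiency(w[nb, nb, drop = FALSE])
  }
  setNames(out, rownames(w))
}

#' Area under a nodal metric's sparsity curve
#'
#' Trapezoidal integral of a metric over the sparsity sweep, the
#' threshold-free summary used instead of committing to a single sparsity.
#'
#' @param values Metric values, one per sparsity, in sweep order.
#' @param sparsities The sweep (default 0.05 to 0.5, step 0.05); `values`
#'   must cover every point.
#' @return The AUC over the sweep interval.
#' @export
metric_auc <- function(values, sparsities = seq(0.05, 0.5, by = 0.05)) {
  if (length(values) != length(sparsities)) {
    stop("need one value per sparsity threshold")
  }
  if (any(is.na(values))) stop("missing metric values")
  h <- diff(sparsities)
  sum((values[-length(values)] + values[-1L]) / 2 * h)
}

#' Nodal metric table over a sparsity sweep
#'
#' The full graph-theoretical stage for one subject's weighted network: the
#' total strength is normalized to 1, the network is thresholded at every
#' sparsity in the sweep, the four weighted nodal metrics (Cp, Dc, Eloc, Eg)
#' are computed per node, and each node-metric curve is summarized by its
#' AUC.
#'
#' @param w Symmetric weight matrix with node labels (e.g. the 10-node
#'   tool-use subnetwork).
#' @param sparsities Sparsity sweep (default 0.05 to 0.5, step 0.05).
#' @param weighted_dc Use strength (default) or binary degree for Dc.
#' @return List with `per_sparsity` (long data.frame: `node`, `sparsity`,
#'   `metric`, `value`) and `auc` (data.frame: `node`, `metric`, `auc`).
#' @export
nodal_metric_table <- function(w, sparsities = seq(0.05, 0.5, by = 0.05),
                               weighted_dc = TRUE) {
  wn <- normalize_total_strength(w)
  labels <- rownames(wn)
  if (is.null(labels)) labels <- sprintf("n%03d", seq_len(nrow(wn)))

  rows <- lapply(sparsities, function(s) {
    wt <- threshold_by_sparsity(wn, s)
    vals <- cbind(
      Cp = nodal_clustering(wt),
      Dc = nodal_degree_centrality(wt, weighted = weighted_dc),
      Eloc = nodal_local_efficiency(wt),
      Eg = nodal_efficiency(wt)
    )
    data.frame(
      node = rep(labels, times = 4L),
      sparsity = s,
      metric = rep(colnames(vals), each = nrow(vals)),
      value = as.vector(vals),
      stringsAsFactors = FALSE
    )
  })
  per_sparsity <- do.call(rbind, rows)

  auc <- do.call(rbind, lapply(labels, function(nd) {
    do.call(rbind, lapply(c("Cp", "Dc", "Eloc", "Eg"), function(m) {
      v <- per_sparsity$value[per_sparsity$node == nd &
                                per_sparsity$metric == m]
      data.frame(node = nd, metric = m,
                 auc = metric_auc(v, sparsities),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(per_sparsity = per_sparsity, auc = auc)
}

#' Extract the tool-use subnetwork from a homolog-space connectome
#'
#' @param w Connectome matrix whose labels include the tool-use node set.
#' @param nodes Node labels (default [tool_use_nodes()]).
#' @return Submatrix over the tool-use nodes.
#' @export
tool_use_subnetwork <- function(w, nodes = tool_use_nodes()) {
  missing <- setdiff(nodes, rownames(w))
  if (length(missing) > 0L) {
    stop("tool-use nodes missing from connectome: ",
         paste(missing, collapse = ", "))
  }
  w[nodes, nodes]
}
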