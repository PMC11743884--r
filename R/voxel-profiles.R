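#' Binarize a streamline visitation count volume
#'
#' A voxel is marked present (1) if at least one streamline visited it, and
#' absent (0) otherwise. No threshold parameter exists: any nonzero count is
#' presence.
#'
#' @param counts 3D array of nonnegative streamline counts.
#' @return Integer 0/1 array of the same shape.
#' @export
binarize_profile <- function(counts) {
  if (any(counts < 0)) stop("streamline counts must be nonnegative")
  array(as.integer(counts > 0), dim = dim(counts))
}

#' Group probabilistic map of binarized profiles
#'
#' For one seed region, combines the subjects' binary profiles into a map
#' whose voxel value is the fraction of subjects in which the voxel is present
#' (0.5 means the voxel is 1 in half of the subjects).
#'
#' @param profiles List of binary 0/1 arrays, one per subject, identical grids
#'   and seed.
#' @return Array of per-voxel subject fractions in \[0, 1\], with attribute
#'   `n_subjects`.
#' @export
group_probability_map <- function(profiles) {
  check_same_grids(profiles)
  for (p in profiles) {
    if (!all(p %in% c(0L, 1L))) stop("profiles must be strictly binary")
  }
  n <- length(profiles)
  acc <- Reduce(`+`, profiles)
  out <- acc / n
  attr(out, "n_subjects") <- n
  out
}

#' Group-average connectivity profile
#'
#' Per-voxel arithmetic mean of the subjects' streamline count volumes, giving
#' the group-level profile used for the dominance classification.
#'
#' @param profiles List of count arrays, one per subject, identical grids and
#'   seed.
#' @return Numeric array of per-voxel mean counts.
#' @export
group_average_profile <- function(profiles) {
  check_same_grids(profiles)
  for (p in profiles) {
    if (any(p < 0)) stop("streamline counts must be nonnegative")
  }
  Reduce(`+`, lapply(profiles, as.numeric_array)) / length(profiles)
}

check_same_grids <- function(profiles) {
  if (length(profiles) < 1L) stop("need at least one profile")
  d <- dim(profiles[[1L]])
  for (p in profiles) {
    if (!identical(dim(p), d)) stop("profiles must share one voxel grid")
  }
  invisible(d)
}

as.numeric_array <- function(x) array(as.numeric(x), dim = dim(x))

#' MPM label codes
#'
#' Integer coding of the modified maximum-probability-map labels:
#' 0 = UNCLASSIFIED (no seed reaches the voxel), 1/2/3 = dominantly connected
#' to MST/MT/FST, 4 = OVERLAP (connected, but no seed dominates).
#'
#' @return Named integer vector.
#' @export
mpm_label_codes <- function() {
  c(UNCLASSIFIED = 0L, MST = 1L, MT = 2L, FST = 3L, OVERLAP = 4L)
}

#' Modified maximum probability map of fiber-tract dominance
#'
#' Classifies each white-matter voxel from the three group-averaged seed
#' strengths \eqn{S_{MST}, S_{MT}, S_{FST}}. A voxel is dominantly connected
#' to seed X when \eqn{S_X} is the unique maximum and, against every other
#' seed Y, \eqn{|S_X - S_Y| > (S_X + S_Y)/2} — equivalently
#' \eqn{S_X > 3 S_Y}. Voxels where all three strengths are zero are
#' UNCLASSIFIED; every other voxel (including exact ties at the maximum) is
#' OVERLAP: connected, but to no single dominant subregion.
#'
#' @param avg_mst,avg_mt,avg_fst Group-averaged strength volumes (identical
#'   grids, nonnegative).
#' @param wm_mask Optional logical array restricting classification to white
#'   matter; voxels outside the mask get `NA`.
#' @return Object of class `mpm_volume`: an integer array coded per
#'   [mpm_label_codes()], with the three averaged strengths kept in the
#'   `strengths` attribute.
#' @export
classify_mpm <- function(avg_mst, avg_mt, avg_fst, wm_mask = NULL) {
  check_same_grids(list(avg_mst, avg_mt, avg_fst))
  if (any(avg_mst < 0) || any(avg_mt < 0) || any(avg_fst < 0)) {
    stop("averaged strengths must be nonnegative")
  }
  d <- dim(avg_mst)
  S <- cbind(as.numeric(avg_mst), as.numeric(avg_mt), as.numeric(avg_fst))

  smax <- pmax(S[, 1L], S[, 2L], S[, 3L])
  labels <- rep(mpm_label_codes()[["OVERLAP"]], nrow(S))
  labels[smax == 0] <- mpm_label_codes()[["UNCLASSIFIED"]]
  for (k in 1:3) {
    others <- S[, -k, drop = FALSE]
    ## unique maximum + pairwise three-fold dominance against each other seed
    dominant <- S[, k] > others[, 1L] & S[, k] > others[, 2L] &
      S[, k] > 3 * others[, 1L] & S[, k] > 3 * others[, 2L]
    labels[dominant] <- k
  }

  out <- array(labels, dim = d)
  if (!is.null(wm_mask)) {
    if (!identical(dim(wm_mask), d)) stop("wm_mask grid mismatch")
    out[!wm_mask] <- NA_integer_
  }
  structure(out, class = "mpm_volume",
            strengths = list(MST = avg_mst, MT = avg_mt, FST = avg_fst))
}

#' Percentage of overlap voxels in an MPM
#'
#' Fraction (in percent) of OVERLAP voxels among all classified voxels
#' (dominant MST/MT/FST or OVERLAP). Voxels that no seed reaches
#' (UNCLASSIFIED) and voxels outside the mask are excluded from the
#' denominator.
#'
#' @param mpm An `mpm_volume` from [classify_mpm()].
#' @return Percentage in \[0, 100\]; `NaN` with a warning when no voxel is
#'   classified.
#' @export
overlap_fraction <- function(mpm) {
  codes <- mpm_label_codes()
  lab <- as.integer(mpm)
  lab <- lab[!is.na(lab)]
  classified <- lab != codes[["UNCLASSIFIED"]]
  if (!any(classified)) {
    warning("no classified voxels; overlap fraction undefined")
    return(NaN)
  }
  100 * sum(lab == codes[["OVERLAP"]]) / sum(classified)
}
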