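#' Pairwise Dice overlap of two binary voxel sets
#'
#' \deqn{Dice(A, B) = \frac{2 V_{overlap}}{V_A + V_B}} where
#' \eqn{V_{overlap}} is the number of voxels present in both sets and
#' \eqn{V_A, V_B} are the set sizes. Inputs may be binary arrays (optionally
#' restricted to a tissue mask) or explicit voxel index vectors; the metric
#' itself is tissue-agnostic — the caller chooses gray- or white-matter
#' restriction.
#'
#' @param a,b Binary 0/1 arrays on one grid, or integer index vectors.
#' @param mask Optional logical array restricting both inputs (array form
#'   only).
#' @return Coefficient in \[0, 1\]; `NA` with a warning when both sets are
#'   empty (the coefficient is undefined there).
#' @export
dice_pair <- function(a, b, mask = NULL) {
  s <- as_voxel_sets(list(a, b), mask)
  va <- length(s[[1L]])
  vb <- length(s[[2L]])
  if (va + vb == 0L) {
    warning("both voxel sets empty; Dice undefined")
    return(NA_real_)
  }
  2 * length(intersect(s[[1L]], s[[2L]])) / (va + vb)
}

#' Third-order Dice overlap of three binary voxel sets
#'
#' \deqn{Dice(A, B, C) = \frac{3 V_{overlap}}{V_A + V_B + V_C}} where
#' \eqn{V_{overlap}} counts the voxels present in all three sets. This is the
#' single-number summary of how similar three connectivity profiles are.
#'
#' @inheritParams dice_pair
#' @param c Third binary array or index vector.
#' @return Coefficient in \[0, 1\]; `NA` with a warning when all sets are
#'   empty.
#' @export
dice_third_order <- function(a, b, c, mask = NULL) {
  s <- as_voxel_sets(list(a, b, c), mask)
  vtot <- sum(lengths(s))
  if (vtot == 0L) {
    warning("all voxel sets empty; third-order Dice undefined")
    return(NA_real_)
  }
  v3 <- length(intersect(intersect(s[[1L]], s[[2L]]), s[[3L]]))
  3 * v3 / vtot
}

## Normalize array/index inputs to unique voxel index vectors on one grid.
as_voxel_sets <- function(inputs, mask = NULL) {
  is_arr <- vapply(inputs, function(x) !is.null(dim(x)), logical(1L))
  if (any(is_arr) && !all(is_arr)) {
    stop("mix of array and index inputs is not supported")
  }
  if (all(is_arr)) {
    d <- dim(inputs[[1L]])
    for (x in inputs) {
      if (!identical(dim(x), d)) stop("voxel grids do not match")
      if (!all(x %in% c(0L, 1L))) stop("arrays must be strictly binary")
    }
    if (!is.null(mask)) {
      if (!identical(dim(mask), d)) stop("mask grid mismatch")
      inputs <- lapply(inputs, function(x) which(x > 0 & mask))
    } else {
      inputs <- lapply(inputs, function(x) which(x > 0))
    }
    inputs
  } else {
    if (!is.null(mask)) stop("mask is only supported for array inputs")
    lapply(inputs, function(x) unique(as.integer(x)))
  }
}

#' Per-subject Dice table for a set of binarized seed profiles
#'
#' Computes, for every subject, the three pairwise Dice coefficients between
#' seed profiles and the third-order Dice across all three, restricted to a
#' tissue mask. Output is tidy (one row per subject and comparison), ready for
#' external repeated-measures statistics.
#'
#' @param profile_set A `synthetic_profiles` object (or any list with
#'   `profiles[[subject]][[seed]]` count arrays).
#' @param mask Logical array selecting the tissue of interest (gray or white
#'   matter).
#' @param tissue Label stored in the output (e.g. `"GM"`).
#' @return data.frame with columns `subject`, `tissue`, `comparison`, `dice`.
#' @export
dice_table <- function(profile_set, mask, tissue = "GM") {
  seeds <- mt_seeds()
  pairs <- utils::combn(seeds, 2L)
  rows <- lapply(names(profile_set$profiles), function(sub) {
    bin <- lapply(profile_set$profiles[[sub]], binarize_profile)
    pw <- vapply(seq_len(ncol(pairs)), function(j) {
      dice_pair(bin[[pairs[1L, j]]], bin[[pairs[2L, j]]], mask = mask)
    }, numeric(1L))
    d3 <- dice_third_order(bin[[1L]], bin[[2L]], bin[[3L]], mask = mask)
    data.frame(
      subject = sub,
      tissue = tissue,
      comparison = c(paste(pairs[1L, ], pairs[2L, ], sep = "-"), "MST-MT-FST"),
      dice = c(pw, d3),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
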