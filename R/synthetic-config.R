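#' Configuration for the synthetic connectivity generator
#'
#' Bundles every knob of the synthetic-data module. The generator emulates the
#' data structure of a two-species MT+ tractography study: per-subject,
#' per-seed streamline visitation count volumes on a voxel grid, and
#' per-subject ROI-by-ROI streamline-count matrices with known ground-truth
#' similarity structure.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_regions Number of target regions outside the three MT+ seeds
#'   (>= 4).
#' @param target_pattern_correlation 3x3 symmetric matrix in \[-1, 1\] with
#'   unit diagonal: the desired inter-seed Spearman correlation of the latent
#'   seed-to-target connectivity vectors. Must be positive semidefinite.
#'   A scalar is expanded to a compound-symmetric matrix.
#' @param subject_noise_sd Nonnegative standard deviation (log scale) of the
#'   multiplicative log-normal between-subject noise.
#' @param grid_shape Integer vector of 3 voxel-grid dimensions (each >= 4).
#'   The third axis is the dorso-ventral axis.
#' @param gradient_strength Nonnegative logistic slope of the dorso-ventral
#'   location dependence of seed dominance. 0 gives identical expected spatial
#'   profiles for all seeds (human-like); large values give disjoint
#'   dorsal/middle/ventral bands for MST/MT/FST (macaque-like).
#' @param mean_count Positive expected streamline count scale at the grid
#'   centre.
#' @param rng_seed Integer seed controlling all randomness.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [human_like_config()], [macaque_like_config()]
#' @export
synthetic_config <- function(n_subjects = 30L,
                             n_regions = 80L,
                             target_pattern_correlation = 0.5,
                             subject_noise_sd = 0.3,
                             grid_shape = c(12L, 12L, 12L),
                             gradient_strength = 0,
                             mean_count = 40,
                             rng_seed = 1L) {
  if (length(target_pattern_correlation) == 1L) {
    r <- target_pattern_correlation
    target_pattern_correlation <- matrix(r, 3L, 3L)
    diag(target_pattern_correlation) <- 1
  }
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_regions = as.integer(n_regions),
      n_seeds = 3L,
      target_pattern_correlation = target_pattern_correlation,
      subject_noise_sd = subject_noise_sd,
      grid_shape = as.integer(grid_shape),
      gradient_strength = gradient_strength,
      mean_count = mean_count,
      rng_seed = as.integer(rng_seed)
    ),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_subjects < 2L) stop("n_subjects must be >= 2")
  if (cfg$n_regions < 4L) stop("n_regions must be >= 4")
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 4L)) {
    stop("grid_shape must be 3 integers, each >= 4")
  }
  if (cfg$subject_noise_sd < 0) stop("subject_noise_sd must be >= 0")
  if (cfg$gradient_strength < 0) stop("gradient_strength must be >= 0")
  if (cfg$mean_count <= 0) stop("mean_count must be > 0")
  R <- cfg$target_pattern_correlation
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L))) {
    stop("target_pattern_correlation must be a 3x3 matrix")
  }
  if (max(abs(R - t(R))) > 1e-12) {
    stop("target_pattern_correlation must be symmetric")
  }
  if (max(abs(diag(R) - 1)) > 1e-12) {
    stop("target_pattern_correlation must have a unit diagonal")
  }
  if (any(abs(R) > 1 + 1e-12)) {
    stop("target_pattern_correlation entries must lie in [-1, 1]")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(
      "target_pattern_correlation is not positive semidefinite (min eigenvalue %.3g)",
      min(ev)
    ))
  }
  invisible(cfg)
}

#' Human-like and macaque-like study conditions
#'
#' Convenience constructors for the two species conditions of the synthetic
#' experiment. The human-like condition has no dorso-ventral location
#' dependence and highly correlated inter-seed connectivity patterns
#' (off-diagonal target Spearman 0.9); the macaque-like condition has a strong
#' dorso-ventral gradient (MST dorsal, MT middle, FST ventral) and weakly
#' correlated patterns (0.2).
#'
#' @param n_subjects Number of subjects.
#' @param rng_seed Integer seed.
#' @param ... Further arguments passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
human_like_config <- function(n_subjects = 30L, rng_seed = 1L, ...) {
  synthetic_config(
    n_subjects = n_subjects,
    target_pattern_correlation = 0.9,
    gradient_strength = 0,
    rng_seed = rng_seed,
    ...
  )
}

#' @rdname human_like_config
#' @export
macaque_like_config <- function(n_subjects = 30L, rng_seed = 1L, ...) {
  synthetic_config(
    n_subjects = n_subjects,
    target_pattern_correlation = 0.2,
    gradient_strength = 30,
    rng_seed = rng_seed,
    ...
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic connectivity configuration\n")
  cat(sprintf("  subjects: %d, target regions: %d (+ 3 seeds)\n",
              x$n_subjects, x$n_regions))
  cat(sprintf("  grid: %s, gradient strength: %g, mean count: %g\n",
              paste(x$grid_shape, collapse = "x"),
              x$gradient_strength, x$mean_count))
  cat(sprintf("  off-diagonal target Spearman: %s; noise sd: %g; seed: %d\n",
              paste(unique(round(x$target_pattern_correlation[
                upper.tri(x$target_pattern_correlation)], 3)), collapse = ", "),
              x$subject_noise_sd, x$rng_seed))
  invisible(x)
}
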