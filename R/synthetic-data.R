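#' Generate multi-subject synthetic ROI connectomes with known ground truth
#'
#' Draws a latent "true" connectome whose three seed rows (MST, MT, FST) have
#' a controllable inter-seed Spearman correlation, then produces per-subject
#' raw streamline-count matrices around it under multiplicative log-normal
#' noise.
#'
#' The latent seed-to-target vectors are built with a Gaussian copula: a
#' trivariate normal with Pearson correlation `2*sin(pi*rho/6)` (the exact
#' normal-copula inverse of a Spearman target `rho`) is pushed through
#' log-normal marginals, so strengths are positive, right-skewed, and their
#' rank correlations converge to `target_pattern_correlation` as the number of
#' target regions grows. Latent values live on the size-normalized scale;
#' raw subject counts are scaled back up by the mean node volume of each
#' region pair so that [normalize_by_node_size()] recovers the latent scale.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_connectomes` with elements:
#'   \describe{
#'     \item{subjects}{list of `n_subjects` symmetric raw-count matrices
#'       (zero diagonal, labelled).}
#'     \item{node_volumes}{named positive node volumes (shared across
#'       subjects).}
#'     \item{latent}{the latent size-normalized connectome matrix.}
#'     \item{truth_seed_vectors}{3 x n_regions matrix of latent seed-to-target
#'       strengths (the ground truth the pipeline should recover).}
#'     \item{labels, seed_labels, config}{bookkeeping.}
#'   }
#' @export
generate_roi_connectomes <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$rng_seed + 11L)

  seeds <- mt_seeds()
  targets <- sprintf("R%03d", seq_len(config$n_regions))
  labels <- c(seeds, targets)
  n_all <- length(labels)
  nt <- config$n_regions

  ## Spearman target -> Pearson correlation of the latent normal scores
  Rp <- 2 * sin(pi * config$target_pattern_correlation / 6)
  ed <- eigen(Rp, symmetric = TRUE)
  if (min(ed$values) < -1e-8) {
    stop("target_pattern_correlation maps to a non-PSD normal-score correlation")
  }
  ## symmetric matrix square root: exact for singular (perfect-correlation)
  ## targets, where a Cholesky factor is numerically unstable
  Rp_sqrt <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
  Z <- matrix(rnorm(nt * 3L), nt, 3L) %*% Rp_sqrt
  ## a perfect rank-correlation target is the copy (or mirror) copula; make
  ## it exact rather than leaving it to floating-point round-off
  Rs <- config$target_pattern_correlation
  for (j in 1:2) {
    for (k in seq(j + 1L, 3L)) {
      if (Rs[j, k] == 1) Z[, k] <- Z[, j]
      if (Rs[j, k] == -1) Z[, k] <- -Z[, j]
    }
  }

  meanlog <- log(config$mean_count)
  sdlog <- 1
  S <- qlnorm(pnorm(Z), meanlog = meanlog, sdlog = sdlog)  # nt x 3
  colnames(S) <- seeds

  latent <- matrix(0, n_all, n_all, dimnames = list(labels, labels))
  latent[seeds, targets] <- t(S)
  latent[targets, seeds] <- S
  ## seed-seed and target-target background edges: independent log-normals
  ss <- qlnorm(pnorm(rnorm(3L)), meanlog, sdlog)
  latent["MST", "MT"] <- latent["MT", "MST"] <- ss[1L]
  latent["MST", "FST"] <- latent["FST", "MST"] <- ss[2L]
  latent["MT", "FST"] <- latent["FST", "MT"] <- ss[3L]
  tt <- qlnorm(pnorm(rnorm(nt * (nt - 1L) / 2L)), meanlog, sdlog)
  tt_block <- matrix(0, nt, nt)
  tt_block[upper.tri(tt_block)] <- tt
  tt_block <- tt_block + t(tt_block)
  latent[targets, targets] <- tt_block
  diag(latent) <- 0

  node_volumes <- setNames(exp(rnorm(n_all, log(100), 0.3)), labels)
  vol_scale <- outer(node_volumes, node_volumes, "+") / 2

  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    noise <- matrix(0, n_all, n_all)
    noise[upper.tri(noise)] <-
      rnorm(n_all * (n_all - 1L) / 2L, 0, config$subject_noise_sd)
    noise <- exp(noise + t(noise))
    m <- latent * vol_scale * noise
    diag(m) <- 0
    dimnames(m) <- list(labels, labels)
    subjects[[i]] <- m
  }
  names(subjects) <- sprintf("sub%02d", seq_len(config$n_subjects))

  structure(
    list(
      subjects = subjects,
      node_volumes = node_volumes,
      latent = latent,
      truth_seed_vectors = latent[seeds, targets],
      labels = labels,
      seed_labels = seeds,
      config = config
    ),
    class = "synthetic_connectomes"
  )
}

## Dorso-ventral band weight of each seed: a logistic bump along the
## normalized dorso-ventral coordinate t in (0,1). Bands are
## MST dorsal (2/3, 4/3), MT middle (1/3, 2/3), FST ventral (-1/3, 1/3);
## at gradient 0 every band collapses to the same constant 0.25.
seed_band_weight <- function(t, seed, gradient_strength) {
  bounds <- switch(seed,
    MST = c(2 / 3, 4 / 3),
    MT  = c(1 / 3, 2 / 3),
    FST = c(-1 / 3, 1 / 3),
    stop("unknown seed: ", seed)
  )
  plogis(gradient_strength * (t - bounds[1L])) *
    plogis(gradient_strength * (bounds[2L] - t))
}

#' Generate multi-subject synthetic voxel-level connectivity profiles
#'
#' Produces, for each subject and each MT+ seed, a 3D volume of streamline
#' visitation counts, together with gray- and white-matter masks on the same
#' grid. Expected counts are a deterministic spatial rate field (a radial
#' intensity falloff times a seed-specific dorso-ventral band weight) times a
#' per-subject log-normal multiplier; observed counts are Poisson draws around
#' that rate, so they are nonnegative integers with realistic presence/absence
#' variability at the periphery.
#'
#' With `gradient_strength = 0` all three seeds share one expected spatial
#' profile (human-like); with a large gradient MST/MT/FST concentrate in the
#' dorsal/middle/ventral thirds of the dorso-ventral axis (macaque-like,
#' grid axis 3).
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_profiles` with elements `profiles`
#'   (list per subject of a list per seed of 3D integer count arrays),
#'   `gm_mask`, `wm_mask` (logical arrays), `rates` (expected count array per
#'   seed), and `config`.
#' @export
generate_voxel_profiles <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$rng_seed + 23L)

  d <- config$grid_shape
  seeds <- mt_seeds()

  ## deterministic radial intensity field over the two in-plane axes
  u1 <- (seq_len(d[1L]) - 0.5) / d[1L] - 0.5
  u2 <- (seq_len(d[2L]) - 0.5) / d[2L] - 0.5
  base2d <- exp(-outer(u1^2, u2^2, "+") / (2 * 0.25^2))
  tcoord <- (seq_len(d[3L]) - 0.5) / d[3L]  # 0 = ventral, 1 = dorsal

  rates <- lapply(seeds, function(s) {
    w <- seed_band_weight(tcoord, s, config$gradient_strength)
    r <- array(0, dim = d)
    for (k in seq_len(d[3L])) r[, , k] <- config$mean_count * 4 * w[k] * base2d
    r
  })
  names(rates) <- seeds

  profiles <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    per_seed <- lapply(seeds, function(s) {
      mult <- exp(rnorm(1L, 0, config$subject_noise_sd))
      array(rpois(prod(d), rates[[s]] * mult), dim = d)
    })
    names(per_seed) <- seeds
    profiles[[i]] <- per_seed
  }
  names(profiles) <- sprintf("sub%02d", seq_len(config$n_subjects))

  ## synthetic tissue split along grid axis 1: inner half white matter,
  ## outer half gray matter (no anatomical realism intended)
  idx1 <- slice.index(array(0L, dim = d), 1L)
  wm_mask <- idx1 <= floor(d[1L] / 2)
  gm_mask <- !wm_mask

  structure(
    list(
      profiles = profiles,
      gm_mask = gm_mask,
      wm_mask = wm_mask,
      rates = rates,
      config = config
    ),
    class = "synthetic_profiles"
  )
}

#' Generate a synthetic directed tracer-strength table
#'
#' Emulates a retrograde-tracer connectivity table for one injected seed
#' region: for every other region connected to the seed in the ground-truth
#' connectome, two directed entries (region -> seed and seed -> region) are
#' produced, each equal to the true undirected strength times independent
#' multiplicative log-normal noise. With `noise_sd = 0` both directions
#' reproduce the truth exactly.
#'
#' @param config A [synthetic_config()] (supplies the RNG seed).
#' @param truth Symmetric labelled ground-truth strength matrix (for example
#'   the `latent` element of [generate_roi_connectomes()]).
#' @param seed Injected seed region label (default `"MT"`).
#' @param noise_sd Log-scale noise standard deviation; defaults to
#'   `config$subject_noise_sd`.
#' @return A data.frame with columns `source`, `target`, `strength` (one row
#'   per directed connection involving the seed).
#' @export
generate_tracer_table <- function(config, truth, seed = "MT",
                                  noise_sd = config$subject_noise_sd) {
  validate_synthetic_config(config)
  if (!is.matrix(truth) || nrow(truth) != ncol(truth) ||
      max(abs(truth - t(truth))) > 1e-8) {
    stop("truth must be a symmetric matrix")
  }
  if (!seed %in% rownames(truth)) stop("seed not found in truth labels")
  set.seed(config$rng_seed + 37L)

  others <- setdiff(rownames(truth), seed)
  strength <- truth[others, seed]
  incoming <- strength * exp(rnorm(length(others), 0, noise_sd))
  outgoing <- strength * exp(rnorm(length(others), 0, noise_sd))
  data.frame(
    source = c(others, rep(seed, length(others))),
    target = c(rep(seed, length(others)), others),
    strength = c(incoming, outgoing),
    stringsAsFactors = FALSE
  )
}
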