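#' Default homologous-region table
#'
#' Loads the packaged 27-row homology configuration mapping species atlas
#' labels to shared homolog names with lobe assignments. The packaged default
#' is an editable stand-in built from regions commonly treated as
#' human-macaque homologs (premotor, intraparietal, superior temporal, and
#' early visual areas); real analyses should replace the `atlas_label` column
#' with the labels of their own parcellations (many-to-one label-to-homolog
#' mappings are allowed, aggregated by summation).
#'
#' @param path Optional path to an alternative table (TSV with columns
#'   `species`, `atlas_label`, `homolog`, `lobe`).
#' @return data.frame with one row per (species, atlas_label).
#' @export
homology_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "homologous_regions.tsv",
                        package = "mtplusconn", mustWork = TRUE)
  }
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "", comment.char = "#")
  required <- c("species", "atlas_label", "homolog", "lobe")
  if (!all(required %in% names(tab))) {
    stop("homology table needs columns: ", paste(required, collapse = ", "))
  }
  ok_lobes <- c("frontal", "parietal", "temporal", "occipital")
  if (!all(tab$lobe %in% ok_lobes)) stop("unknown lobe in homology table")
  tab
}

#' Make a homology table for a synthetic connectome
#'
#' Maps the first 27 synthetic target region labels of both species onto the
#' default homolog names, giving the synthetic pipeline a valid common space.
#'
#' @param labels Region labels of the synthetic connectome (seeds excluded
#'   automatically).
#' @return Homology table data.frame covering species `"human"` and
#'   `"macaque"`.
#' @export
synthetic_homology_table <- function(labels) {
  base <- homology_table()
  homologs <- unique(base[, c("homolog", "lobe")])
  targets <- setdiff(labels, mt_seeds())
  if (length(targets) < nrow(homologs)) {
    stop("need at least ", nrow(homologs), " target regions")
  }
  do.call(rbind, lapply(c("human", "macaque"), function(sp) {
    data.frame(
      species = sp,
      atlas_label = targets[seq_len(nrow(homologs))],
      homolog = homologs$homolog,
      lobe = homologs$lobe,
      stringsAsFactors = FALSE
    )
  }))
}

#' Project a connectome onto the homologous-region common space
#'
#' Computes the connection strength between each MT+ seed and each of the 27
#' homologous regions by summing the weights from the seed to every atlas
#' label mapped to that homolog (strengths are extensive, so many-to-one
#' mappings aggregate additively). Joint ranks are assigned over the full
#' 3 x 27 strength table at once (average ranks on ties), matching the joint
#' ranking used to display seed fingerprints on a common radial scale.
#'
#' @param connectome Labelled connectome matrix (group-level or per subject).
#' @param homology Homology table (see [homology_table()]).
#' @param species Species name selecting rows of `homology`.
#' @param seeds Seed labels.
#' @return Object of class `common_space_profile`: list with `strengths` and
#'   `joint_ranks` (3 x n_homolog matrices), `species`, `lobes`.
#' @export
project_to_common_space <- function(connectome, homology, species,
                                    seeds = mt_seeds()) {
  hom <- homology[homology$species == species, , drop = FALSE]
  if (nrow(hom) == 0L) stop("no homology rows for species ", species)
  missing <- setdiff(hom$atlas_label, colnames(connectome))
  if (length(missing) > 0L) {
    stop("atlas labels missing from connectome: ",
         paste(missing, collapse = ", "))
  }
  homologs <- unique(hom$homolog)
  strengths <- matrix(0, length(seeds), length(homologs),
                      dimnames = list(seeds, homologs))
  for (h in homologs) {
    labs <- hom$atlas_label[hom$homolog == h]
    strengths[, h] <- rowSums(connectome[seeds, labs, drop = FALSE])
  }
  joint <- matrix(rank(strengths), nrow(strengths), ncol(strengths),
                  dimnames = dimnames(strengths))
  lobes <- setNames(hom$lobe[!duplicated(hom$homolog)], homologs)
  structure(
    list(strengths = strengths, joint_ranks = joint,
         species = species, lobes = lobes),
    class = "common_space_profile"
  )
}

#' Cross-species correlation of a seed's homologous-region fingerprint
#'
#' Spearman correlation between one seed's strength profile over the 27
#' homologous regions in the two species, Bonferroni-corrected for the three
#' seeds tested.
#'
#' @param profile_a,profile_b `common_space_profile`s for the two species.
#' @param seed Seed label.
#' @param n_tests Bonferroni family size (default 3).
#' @return List with `rho`, `p_value`, `p_adjusted`, `n_homologs`.
#' @export
cross_species_seed_correlation <- function(profile_a, profile_b, seed,
                                           n_tests = 3L) {
  if (!identical(colnames(profile_a$strengths),
                 colnames(profile_b$strengths))) {
    stop("homolog lists must be aligned across species")
  }
  va <- profile_a$strengths[seed, ]
  vb <- profile_b$strengths[seed, ]
  r <- seed_pattern_correlation(va, vb, n_tests = n_tests)
  list(rho = r$rho, p_value = r$p_value, p_adjusted = r$p_adjusted,
       n_homologs = r$n_targets)
}

#' Long-format export of a common-space profile
#'
#' @param profile A `common_space_profile`.
#' @return data.frame with columns `species`, `seed`, `homolog`, `lobe`,
#'   `strength`, `joint_rank` (spider-plot-ready).
#' @export
common_space_long <- function(profile) {
  seeds <- rownames(profile$strengths)
  homologs <- colnames(profile$strengths)
  data.frame(
    species = profile$species,
    seed = rep(seeds, times = length(homologs)),
    homolog = rep(homologs, each = length(seeds)),
    lobe = rep(unname(profile$lobes[homologs]), each = length(seeds)),
    strength = as.vector(profile$strengths),
    joint_rank = as.vector(profile$joint_ranks),
    stringsAsFactors = FALSE
  )
}

#' Collapse a directed tracer table to undirected strengths
#'
#' For every unordered region pair, the undirected strength is the mean of
#' the two directed entries when both exist, or the single existing entry
#' otherwise (diffusion tractography cannot resolve direction, so the tracer
#' side is averaged to match).
#'
#' @param tracer data.frame with columns `source`, `target`, `strength`
#'   (at most one row per ordered pair).
#' @return data.frame with columns `region_a`, `region_b`, `strength`
#'   (`region_a < region_b`).
#' @export
symmetrize_tracer <- function(tracer) {
  stopifnot(all(c("source", "target", "strength") %in% names(tracer)))
  key_ordered <- paste(tracer$source, tracer$target, sep = "\r")
  if (anyDuplicated(key_ordered)) {
    stop("tracer table has duplicate ordered pairs")
  }
  a <- pmin(tracer$source, tracer$target)
  b <- pmax(tracer$source, tracer$target)
  key <- paste(a, b, sep = "\r")
  agg <- tapply(tracer$strength, key, mean)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(
    region_a = vapply(parts, `[`, "", 1L),
    region_b = vapply(parts, `[`, "", 2L),
    strength = as.numeric(agg),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Concordance between a tractography seed vector and tracer strengths
#'
#' Validates diffusion-based connection strengths of one seed against a
#' directed tracer table: directed tracer entries are averaged to undirected
#' strengths (optionally skipped when the tracer study measured only one
#' direction), tracer regions are aggregated onto atlas regions by summation
#' via `region_mapping`, unmappable regions are dropped, and the Spearman
#' correlation over the shared region set is returned.
#'
#' @param dti_seed_vector Named vector of tractography strengths from the
#'   seed to atlas regions.
#' @param tracer Directed tracer table (`source`, `target`, `strength`).
#' @param seed Seed region label in the tracer table.
#' @param region_mapping Optional named character vector mapping tracer
#'   region names to atlas region names (unmapped tracer regions are
#'   dropped); `NULL` means tracer names are already atlas names.
#' @param symmetrize Average bidirectional tracer entries (default `TRUE`);
#'   set `FALSE` for seeds whose tracer strengths exist in one direction
#'   only.
#' @return List with `rho`, `p_value`, `n_regions` (shared region count).
#' @export
tracer_concordance <- function(dti_seed_vector, tracer, seed = "MT",
                               region_mapping = NULL, symmetrize = TRUE) {
  if (symmetrize) {
    und <- symmetrize_tracer(tracer)
    keep <- und$region_a == seed | und$region_b == seed
    und <- und[keep, , drop = FALSE]
    region <- ifelse(und$region_a == seed, und$region_b, und$region_a)
    strength <- und$strength
  } else {
    keep <- tracer$source == seed | tracer$target == seed
    t2 <- tracer[keep, , drop = FALSE]
    region <- ifelse(t2$source == seed, t2$target, t2$source)
    strength <- t2$strength
  }

  if (!is.null(region_mapping)) {
    mapped <- region_mapping[region]
    drop <- is.na(mapped)
    region <- unname(mapped[!drop])
    strength <- strength[!drop]
  }
  agg <- tapply(strength, region, sum)

  shared <- intersect(names(agg), names(dti_seed_vector))
  if (length(shared) < 3L) stop("fewer than 3 shared regions after mapping")
  ct <- suppressWarnings(
    cor.test(dti_seed_vector[shared], as.numeric(agg[shared]),
             method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_regions = length(shared))
}
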