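#' Run the voxel-level analysis arm
#'
#' Chains the voxel-level stages on one species' data: per-subject profile
#' binarization, per-subject pairwise and third-order Dice in gray and white
#' matter, group probabilistic maps, group-average profiles, the modified MPM
#' dominance classification of white-matter voxels, and the overlap
#' percentage.
#'
#' @param config A [synthetic_config()] describing the species condition, or
#'   an existing `synthetic_profiles` object.
#' @param out_dir Optional output directory; when given, Dice tables (TSV),
#'   group maps and the MPM (NIfTI) plus a YAML manifest are written there.
#' @return List with `dice_gm`, `dice_wm` (tidy per-subject tables),
#'   `prob_maps`, `group_avg` (per-seed volumes), `mpm`, `overlap_pct`, and
#'   the generated `profiles`.
#' @export
run_voxel_arm <- function(config, out_dir = NULL) {
  prof <- if (inherits(config, "synthetic_profiles")) config
          else generate_voxel_profiles(config)
  if (length(prof$profiles) == 0L) stop("empty subject list")
  seeds <- mt_seeds()

  dice_gm <- dice_table(prof, prof$gm_mask, tissue = "GM")
  dice_wm <- dice_table(prof, prof$wm_mask, tissue = "WM")

  prob_maps <- lapply(seeds, function(s) {
    group_probability_map(lapply(prof$profiles, function(p) {
      binarize_profile(p[[s]])
    }))
  })
  names(prob_maps) <- seeds

  group_avg <- lapply(seeds, function(s) {
    group_average_profile(lapply(prof$profiles, `[[`, s))
  })
  names(group_avg) <- seeds

  mpm <- classify_mpm(group_avg$MST, group_avg$MT, group_avg$FST,
                      wm_mask = prof$wm_mask)
  overlap_pct <- overlap_fraction(mpm)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(dice_gm, file.path(out_dir, "dice_gm.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(dice_wm, file.path(out_dir, "dice_wm.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (s in seeds) {
      write_volume(prob_maps[[s]],
                   file.path(out_dir, sprintf("probmap_%s.nii.gz", s)))
      write_volume(group_avg[[s]],
                   file.path(out_dir, sprintf("groupavg_%s.nii.gz", s)))
    }
    write_volume(mpm, file.path(out_dir, "mpm.nii.gz"))
    write.table(
      data.frame(statistic = "overlap_pct", value = overlap_pct),
      file.path(out_dir, "overlap.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_manifest(prof$config, file.path(out_dir, "manifest.yaml"),
                   extra = list(arm = "voxel"))
  }

  list(
    dice_gm = dice_gm, dice_wm = dice_wm,
    prob_maps = prob_maps, group_avg = group_avg,
    mpm = mpm, overlap_pct = overlap_pct,
    profiles = prof
  )
}

#' Run the ROI-level analysis arm
#'
#' Chains the ROI-level stages for one or two species: node-size
#' normalization and group averaging of per-subject connectomes, selection of
#' each seed's top-connected targets and their union (optionally swept over a
#' range of fractions), within-species seed-pattern correlations
#' (Bonferroni-corrected over 3 pairs x number of species), the
#' within/between-subject similarity sets with Fisher z, projection onto the
#' homologous-region common space with cross-species seed correlations
#' (Bonferroni n = 3), tracer concordance for the MT seed, and weighted
#' nodal graph metrics with sparsity AUC on the 10-node tool-use subnetwork.
#'
#' @param configs Named list of [synthetic_config()]s (typically
#'   `list(human = ..., macaque = ...)`); a single config analyses one
#'   species and skips the cross-species stage with a notice.
#' @param fractions Top-fraction sweep (default 0.5; e.g.
#'   `seq(0.5, 0.2, by = -0.1)` for the robustness sweep).
#' @param sparsities Sparsity sweep for the graph stage.
#' @param out_dir Optional output directory for tidy TSV tables plus a YAML
#'   manifest.
#' @param tracer_noise_sd Log-normal noise of the synthetic tracer table.
#' @return Nested list of per-species results (`group`, `targets_by_fraction`,
#'   `seed_correlations`, `similarity`, `common_space`, `graph`) plus
#'   `cross_species` and `tracer` when two species are supplied.
#' @export
run_roi_arm <- function(configs,
                        fractions = 0.5,
                        sparsities = seq(0.05, 0.5, by = 0.05),
                        out_dir = NULL,
                        tracer_noise_sd = NULL) {
  if (inherits(configs, "synthetic_config")) {
    configs <- list(species1 = configs)
  }
  if (is.null(names(configs)) || any(names(configs) == "")) {
    stop("configs must be a named list (one entry per species)")
  }
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  seeds <- mt_seeds()

  species_results <- lapply(names(configs), function(sp) {
    cfg <- configs[[sp]]
    gen <- generate_roi_connectomes(cfg)
    normed <- lapply(gen$subjects, normalize_by_node_size,
                     node_volumes = gen$node_volumes)
    group <- group_average_connectome(normed)

    targets_by_fraction <- lapply(fractions, function(f) {
      top_fraction_union(group, seeds, f)
    })
    names(targets_by_fraction) <- sprintf("frac_%.2f", fractions)

    seed_cor <- do.call(rbind, lapply(seq_along(fractions), function(fi) {
      targets <- targets_by_fraction[[fi]]
      pairs <- utils::combn(seeds, 2L)
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        r <- seed_pattern_correlation(
          seed_vector(group, pairs[1L, j], targets),
          seed_vector(group, pairs[2L, j], targets),
          n_tests = 3L * length(configs)
        )
        data.frame(
          species = sp, fraction = fractions[fi],
          pair = paste(pairs[1L, j], pairs[2L, j], sep = "-"),
          rho = r$rho, p_value = r$p_value, p_adjusted = r$p_adjusted,
          n_targets = r$n_targets, stringsAsFactors = FALSE
        )
      }))
    }))

    targets <- targets_by_fraction[[1L]]
    seed_mats <- lapply(seeds, function(s) {
      do.call(rbind, lapply(normed, function(m) seed_vector(m, s, targets)))
    })
    names(seed_mats) <- seeds
    similarity <- similarity_set_table(seed_mats)
    similarity$species <- sp

    hom <- synthetic_homology_table(gen$labels)
    hom_sp <- hom[hom$species == ifelse(sp %in% hom$species, sp, "human"), ]
    hom_sp$species <- sp
    common <- project_to_common_space(group, hom_sp, sp)

    ## per-subject homolog-space tool-use networks -> nodal metrics + AUC
    graph_tabs <- lapply(names(normed), function(sub) {
      hw <- aggregate_to_homolog_space(normed[[sub]], hom_sp, sp)
      tu <- tool_use_subnetwork(hw)
      nodal_metric_table(tu, sparsities = sparsities)
    })
    names(graph_tabs) <- names(normed)
    per_sparsity <- do.call(rbind, lapply(names(graph_tabs), function(sub) {
      cbind(species = sp, subject = sub, graph_tabs[[sub]]$per_sparsity)
    }))
    auc <- do.call(rbind, lapply(names(graph_tabs), function(sub) {
      cbind(species = sp, subject = sub, graph_tabs[[sub]]$auc)
    }))

    list(
      generated = gen, normalized = normed, group = group,
      targets_by_fraction = targets_by_fraction,
      seed_correlations = seed_cor,
      similarity = similarity,
      common_space = common,
      graph = list(per_sparsity = per_sparsity, auc = auc)
    )
  })
  names(species_results) <- names(configs)

  cross <- NULL
  if (length(species_results) >= 2L) {
    sp <- names(species_results)[1:2]
    cross <- do.call(rbind, lapply(seeds, function(s) {
      r <- cross_species_seed_correlation(
        species_results[[sp[1L]]]$common_space,
        species_results[[sp[2L]]]$common_space,
        s, n_tests = 3L
      )
      data.frame(seed = s, rho = r$rho, p_value = r$p_value,
                 p_adjusted = r$p_adjusted, n_homologs = r$n_homologs,
                 stringsAsFactors = FALSE)
    }))
  } else {
    message("single species supplied: cross-species comparison skipped")
  }

  ## tracer concordance against the last species' ground truth (the
  ## tracer literature is macaque work)
  sp_tr <- names(configs)[length(configs)]
  gen_tr <- species_results[[sp_tr]]$generated
  if (is.null(tracer_noise_sd)) {
    tracer_noise_sd <- configs[[sp_tr]]$subject_noise_sd
  }
  tracer_tab <- generate_tracer_table(configs[[sp_tr]], gen_tr$latent,
                                      seed = "MT",
                                      noise_sd = tracer_noise_sd)
  dti_mt <- gen_tr$latent["MT", setdiff(gen_tr$labels, "MT")]
  tracer <- c(
    tracer_concordance(dti_mt, tracer_tab, seed = "MT"),
    list(species = sp_tr, noise_sd = tracer_noise_sd)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sp in names(species_results)) {
      res <- species_results[[sp]]
      tag <- function(f) file.path(out_dir, sprintf("%s_%s", sp, f))
      write_connectome(res$group, tag("group_connectome.tsv"))
      write.table(res$seed_correlations, tag("seed_correlations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(res$similarity, tag("similarity_sets.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(common_space_long(res$common_space),
                  tag("common_space.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(res$graph$per_sparsity, tag("graph_metrics.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(res$graph$auc, tag("graph_auc.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(cross)) {
      write.table(cross, file.path(out_dir, "cross_species.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(
      data.frame(statistic = c("rho", "p_value", "n_regions"),
                 value = c(tracer$rho, tracer$p_value, tracer$n_regions)),
      file.path(out_dir, "tracer_concordance.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_manifest(configs, file.path(out_dir, "manifest.yaml"),
                   extra = list(arm = "roi",
                                fractions = fractions,
                                sparsities = sparsities))
  }

  c(species_results, list(cross_species = cross, tracer = tracer))
}

#' Aggregate a connectome onto homolog-space node labels
#'
#' Builds the (seeds + homologs) x (seeds + homologs) matrix whose entries
#' are sums of the original weights over the atlas labels mapped to each
#' homolog (seed rows/columns pass through unchanged). This is the matrix
#' from which the tool-use subnetwork is cut.
#'
#' @param connectome Labelled connectome matrix.
#' @param homology Homology table rows for one species.
#' @param species Species name.
#' @return Labelled symmetric matrix over `c(mt_seeds(), homologs)`.
#' @export
aggregate_to_homolog_space <- function(connectome, homology, species) {
  hom <- homology[homology$species == species, , drop = FALSE]
  if (nrow(hom) == 0L) stop("no homology rows for species ", species)
  missing <- setdiff(hom$atlas_label, colnames(connectome))
  if (length(missing) > 0L) {
    stop("atlas labels missing from connectome: ",
         paste(missing, collapse = ", "))
  }
  seeds <- mt_seeds()
  homologs <- unique(hom$homolog)
  groups <- c(as.list(seeds), lapply(homologs, function(h) {
    hom$atlas_label[hom$homolog == h]
  }))
  out_labels <- c(seeds, homologs)
  n <- length(out_labels)
  out <- matrix(0, n, n, dimnames = list(out_labels, out_labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      out[i, j] <- sum(connectome[groups[[i]], groups[[j]]])
    }
  }
  out
}
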