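#!/usr/bin/env Rscript

# Stage 1 -- generate the synthetic two-species dataset.
#
# Produces, for a human-like condition (no dorso-ventral gradient, inter-seed
# pattern correlation 0.9) and a macaque-like condition (strong gradient,
# correlation 0.2): per-subject, per-seed streamline count volumes plus
# tissue masks (NIfTI), per-subject raw ROI connectome tables with node
# volumes (TSV), and the ground-truth latent connectome of each condition.

suppressPackageStartupMessages(library(mtplusconn))

seed <- 1234L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

configs <- list(
  human = human_like_config(n_subjects = 30L, rng_seed = seed),
  macaque = macaque_like_config(n_subjects = 30L, rng_seed = seed + 1000L)
)

for (sp in names(configs)) {
  cfg <- configs[[sp]]
  message(sprintf("-- %s-like condition (gradient %g, target correlation %g)",
                  sp, cfg$gradient_strength,
                  cfg$target_pattern_correlation[1, 2]))

  prof <- generate_voxel_profiles(cfg)
  vdir <- file.path(out, sp, "volumes")
  dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
  write_volume(prof$gm_mask * 1, file.path(vdir, "gm_mask.nii.gz"))
  write_volume(prof$wm_mask * 1, file.path(vdir, "wm_mask.nii.gz"))
  for (sub in names(prof$profiles)) {
    for (s in mt_seeds()) {
      write_volume(prof$profiles[[sub]][[s]],
                   file.path(vdir, sprintf("%s_%s_counts.nii.gz", sub, s)))
    }
  }
  message(sprintf("   wrote %d count volumes (%s grid) to %s",
                  3L * cfg$n_subjects,
                  paste(cfg$grid_shape, collapse = "x"), vdir))

  gen <- generate_roi_connectomes(cfg)
  cdir <- file.path(out, sp, "connectomes")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  for (sub in names(gen$subjects)) {
    write_connectome(gen$subjects[[sub]],
                     file.path(cdir, sprintf("%s_counts.tsv", sub)))
  }
  write_node_volumes(gen$node_volumes, file.path(cdir, "node_volumes.tsv"))
  write_connectome(gen$latent, file.path(cdir, "ground_truth_latent.tsv"))
  message(sprintf("   wrote %d connectome tables (%d x %d) to %s",
                  cfg$n_subjects, length(gen$labels), length(gen$labels),
                  cdir))
}

write_manifest(configs, file.path(out, "manifest.yaml"),
               extra = list(stage = "simulate"))
message("synthetic dataset complete: ", out)
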