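#!/usr/bin/env Rscript

# Stage 2 -- voxel-level analysis arm.
#
# For each species condition: binarize every subject's per-seed profile,
# compute per-subject pairwise and third-order Dice overlap in gray and white
# matter, build group probabilistic maps and group-average profiles, classify
# white-matter voxels with the modified MPM dominance rule, and report the
# overlap percentage. Ends with the species contrast on third-order
# gray-matter Dice.

suppressPackageStartupMessages(library(mtplusconn))

seed <- 1234L
configs <- list(
  human = human_like_config(n_subjects = 30L, rng_seed = seed),
  macaque = macaque_like_config(n_subjects = 30L, rng_seed = seed + 1000L)
)

arms <- list()
for (sp in names(configs)) {
  arms[[sp]] <- run_voxel_arm(configs[[sp]],
                              out_dir = file.path("results/voxel", sp))
  d3 <- subset(arms[[sp]]$dice_gm, comparison == "MST-MT-FST")$dice
  message(sprintf(
    "-- %s-like: mean third-order GM Dice %.3f (sd %.3f); WM overlap %.1f%%",
    sp, mean(d3), sd(d3), arms[[sp]]$overlap_pct))
}

d3_h <- subset(arms$human$dice_gm, comparison == "MST-MT-FST")$dice
d3_m <- subset(arms$macaque$dice_gm, comparison == "MST-MT-FST")$dice
tt <- t.test(d3_h, d3_m)
message(sprintf(
  "-- species contrast on third-order GM Dice: t(%.1f) = %.2f, p = %.3g",
  tt$parameter, tt$statistic, tt$p.value))
contrast <- data.frame(
  statistic = c("t", "df", "p_value", "mean_human", "mean_macaque"),
  value = c(tt$statistic, tt$parameter, tt$p.value, mean(d3_h), mean(d3_m))
)
write.table(contrast, "results/voxel/species_contrast.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("voxel arm complete: results/voxel/")
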