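#!/usr/bin/env Rscript

# Stage 4 -- graph-theoretical analysis of the tool-use network.
#
# Summarizes the per-subject weighted nodal metrics (Cp, Dc, Eloc, Eg)
# computed over the sparsity sweep 0.05-0.5 on the 10-node tool-use
# subnetwork, comparing the MT+ seeds' AUCs between the species conditions.
# The per-subject tables are produced by the ROI arm; this stage re-runs it
# if needed and writes the group summary.

suppressPackageStartupMessages(library(mtplusconn))

seed <- 1234L
configs <- list(
  human = human_like_config(n_subjects = 30L, rng_seed = seed),
  macaque = macaque_like_config(n_subjects = 30L, rng_seed = seed + 1000L)
)

auc_path <- c(human = "results/roi/human_graph_auc.tsv",
              macaque = "results/roi/macaque_graph_auc.tsv")
auc <- if (all(file.exists(auc_path))) {
  do.call(rbind, lapply(auc_path, read.table, header = TRUE, sep = "\t"))
} else {
  roi <- run_roi_arm(configs, out_dir = "results/roi")
  rbind(roi$human$graph$auc, roi$macaque$graph$auc)
}

dir.create("results/graph", showWarnings = FALSE, recursive = TRUE)
summary_tab <- aggregate(auc ~ species + node + metric, data = auc, mean)
names(summary_tab)[names(summary_tab) == "auc"] <- "mean_auc"
summary_tab$sd_auc <- aggregate(auc ~ species + node + metric,
                                data = auc, sd)$auc
write.table(summary_tab, "results/graph/auc_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("-- mean AUC of nodal metrics for the MT+ seeds")
for (m in c("Cp", "Dc", "Eloc", "Eg")) {
  for (sp in c("human", "macaque")) {
    sel <- summary_tab$species == sp & summary_tab$metric == m &
      summary_tab$node %in% mt_seeds()
    message(sprintf("     %-4s %-8s %.4f", m, sp,
                    mean(summary_tab$mean_auc[sel])))
  }
}
message("graph stage complete: results/graph/auc_summary.tsv")
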