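# mtplusconn

Structural-connectivity comparison of the MT+ complex subregions — MST,
MT and FST — across primate species, from probabilistic-tractography
outputs. The package is aimed at researchers who already have per-seed
streamline visitation count volumes (NIfTI) and ROI×ROI streamline count
matrices for two species and want the downstream comparison pipeline:

* **Voxel level** — thresholdless binarization of connectivity profiles,
  group probabilistic maps, group-average profiles, and a modified
  maximum-probability-map (MPM) classification of white-matter voxels: a
  voxel is dominantly connected to seed *X* iff *S_X* is the unique maximum
  and |S_X − S_Y| > (S_X + S_Y)/2 (equivalently S_X > 3·S_Y) against every
  other seed *Y*; otherwise it is an overlap voxel. Overlap is summarized as
  the percentage of classified voxels.
* **Overlap statistics** — pairwise and third-order Dice coefficients,
  Dice(A,B) = 2·V_overlap/(V_A+V_B) and
  Dice(A,B,C) = 3·V_overlap/(V_A+V_B+V_C), per subject, in gray or white
  matter.
* **ROI level** — inverse-node-volume normalization
  (w_ab = c_ab·2/(V_a+V_b)), group averaging, top-fraction target-union
  selection, Spearman seed-pattern correlations (Bonferroni-corrected), and
  the within/between-subject similarity sets
  Set_{A−A} = {ρ(v_i^A, v_j^A) : i<j} and
  Set_{A−B} = {(ρ(v_i^A,v_j^B)+ρ(v_i^B,v_j^A))/2 : i<j} with Fisher z.
* **Common space** — projection of seed fingerprints onto 27 homologous
  regions (editable mapping table), joint ranking, cross-species Spearman
  correlations, and tracer–tractography concordance with bidirectional
  averaging and many-to-one region aggregation.
* **Tool-use network** — weighted nodal graph metrics (Cp, Dc, Eloc, Eg) on
  the 10-node tool-use subnetwork over a sparsity sweep 0.05–0.5, summarized
  by trapezoidal AUC.

A synthetic-data module generates multi-subject count volumes with a
controllable dorso-ventral dominance gradient and multi-subject connectomes
with controllable inter-seed pattern correlation, so the full pipeline runs
and is tested without imaging data.

## Worked example

The analysis scripts under `analysis/` run the two synthetic species
conditions (human-like: no gradient, inter-seed pattern correlation 0.9;
macaque-like: strong gradient, correlation 0.2; 30 subjects each):

```sh
Rscript analysis/01_simulate.R      # writes NIfTI volumes + connectome TSVs
Rscript analysis/02_voxel_arm.R
Rscript analysis/03_roi_arm.R
Rscript analysis/04_graph_metrics.R
```

`02_voxel_arm.R` prints, for this seed (1234):

```
-- human-like: mean third-order GM Dice 0.973 (sd 0.009); WM overlap 100.0%
-- macaque-like: mean third-order GM Dice 0.029 (sd 0.010); WM overlap 1.4%
-- species contrast on third-order GM Dice: t(57.2) = 386.99, p = 1.66e-99
```

Read: with identical expected profiles the three seeds' gray-matter
footprints coincide almost perfectly (Dice ≈ 0.97) and every white-matter
voxel is an overlap voxel, while the banded macaque-like condition drives
the three profiles apart (Dice ≈ 0.03, overlap 1.4%) — the qualitative
human/macaque contrast the pipeline is built to quantify. `03_roi_arm.R`
then reports weak macaque-like seed-pattern correlations (ρ ≈ 0.05–0.15,
Bonferroni p = 1), similarity sets whose within-seed mean Fisher z (1.42)
clearly exceeds the between-seed mean (0.09), cross-species fingerprint
correlations near 0 (the two synthetic species are generated independently,
so this stage acts as a negative control), and a tracer concordance of
ρ = 0.979 over 82 regions at noise sd 0.3.

The same functions run on real data: read your matrices with
`read_connectome()` / `read_node_volumes()`, volumes with `read_volume()`,
then call `normalize_by_node_size()`, `dice_table()`, `classify_mpm()`,
`similarity_set_table()`, `project_to_common_space()`,
`nodal_metric_table()` etc., or the bundled arms `run_voxel_arm()` /
`run_roi_arm()`.

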