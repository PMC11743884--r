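---
title: "Methods: cross-species structural connectivity of MT+ subregions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species structural connectivity of MT+ subregions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtplusconn)
```

## The analysis problem

The MT+ complex — the motion-sensitive cortical territory comprising MST
(medial superior temporal), MT (middle temporal) and FST (fundus of the
superior temporal sulcus) — is conserved across primates, but its subregions
need not be wired the same way in every species. Given probabilistic
tractography outputs (per-seed streamline visitation count volumes and
ROI-by-ROI streamline count matrices) for two species, this package asks: how
similar are the three subregions' connectivity fingerprints within each
species, how do the fingerprints compare across species in a common space of
homologous regions, and what role does each subregion play in the tool-use
subnetwork?

The package implements the comparison pipeline itself; it does not do
tractography. Diffusion preprocessing, streamline generation and filtering
are upstream concerns, and the pipeline consumes their outputs (NIfTI count
volumes, delimited connectome tables). Because such data are large and
access-restricted, the package also ships a synthetic generator that emulates
the *structure* of those outputs with known ground truth, so every stage is
testable end to end.

## Voxel-level stage

Each subject's per-seed count volume is binarized with no threshold: a voxel
is "connected" iff at least one streamline visited it
(`binarize_profile()`). Group probabilistic maps record the fraction of
subjects in which each voxel is connected; group-average profiles are
per-voxel mean counts.

White-matter voxels are classified with a modified maximum probability map
(`classify_mpm()`). With group-averaged strengths $S_{MST}, S_{MT}, S_{FST}$
at a voxel, seed $X$ dominates when $S_X$ is the unique maximum and, against
every other seed $Y$,

$$|S_X - S_Y| > \frac{S_X + S_Y}{2} \iff S_X > 3\,S_Y ,$$

i.e. dominance is a three-fold strength margin over *both* competitors. The
description from which this rule is taken spells out only the two-region
comparison, so three design points were genuinely open and are pinned here:

* **Generalization to three seeds.** The pairwise condition is applied to the
  unique maximum against each other seed. This is the only reading consistent
  with classifying voxels as either dominantly connected to one subregion or
  overlapping several.
* **All-zero voxels** get a distinct `UNCLASSIFIED` label: "not connected" is
  not the same observation as "connected to multiple seeds".
* **Exact ties at the maximum** are `OVERLAP` — there is no unique dominant
  seed.

The overlap percentage (`overlap_fraction()`) divides OVERLAP voxels by all
*classified* voxels (dominant or overlap), excluding unreached voxels: the
quantity of interest is overlap within the distribution of connection
strength, and including voxels that no seed reaches would dilute it
arbitrarily with mask size.

Profile similarity is quantified per subject with Dice coefficients over
binarized profiles restricted to a tissue mask:

$$Dice(A,B) = \frac{2\,V_{overlap}}{V_A + V_B}, \qquad
  Dice(A,B,C) = \frac{3\,V_{overlap}}{V_A + V_B + V_C},$$

where $V_{overlap}$ counts voxels connected to both (all three) seeds. The
metric is tissue-agnostic; the caller passes the gray-matter mask for
profiles and the white-matter mask for tract maps. Dice on empty inputs is
undefined and returns a flagged `NA` rather than 0.

## ROI-level stage

Raw streamline counts between regions are corrected for region size as
$w_{ab} = c_{ab}\cdot 2/(V_a+V_b)$ (`normalize_by_node_size()`). Only the
*family* of inverse-node-volume conventions is determined by the upstream
tool chain; the exact form is pinned to the inverse mean volume because any
strictly volume-decreasing choice preserves within-seed rankings (all
downstream statistics are rank-based), and isolating the convention in one
function keeps it swappable.

From the group-average connectome, each seed's top `fraction` (default 0.5)
most-connected non-seed regions are selected and the three lists are
unioned (`top_fraction_union()`). Counts use `ceiling` and ranking ties
break by label order, so the union is deterministic and monotone in the
fraction — which is what makes the 0.5 → 0.2 robustness sweep a nested
comparison. Only the three MT+ seeds are excluded from the candidate pool.

Seed-pattern similarity within species is the average-rank Spearman
correlation between two seeds' group-level connectivity vectors, Bonferroni
corrected (default family of 6: three seed pairs in two species).
Parcellation validity is assessed with the similarity sets

$$Set_{A\text{-}A} = \{\rho(v_i^A, v_j^A) : i<j\}, \qquad
  Set_{A\text{-}B} = \Big\{\tfrac{\rho(v_i^A, v_j^B) +
  \rho(v_i^B, v_j^A)}{2} : i<j\Big\},$$

over subjects $i,j$, each element Fisher z-transformed
(`similarity_sets()`). If the parcellation is meaningful, within-seed sets
should exceed between-seed sets. The Fisher transform clips $\rho$ at
$\pm(1-10^{-7})$: degenerate synthetic inputs can produce exact $\rho = 1$,
and an infinite z would poison downstream means.

## Common space and tracer concordance

Cross-species comparison happens in a common space of 27 homologous
regions. The packaged table (`homology_table()`) is an *editable
configuration*: the 27 names and lobe assignments follow regions widely
treated as human–macaque homologs (premotor, intraparietal, superior
temporal, early visual areas), with identity atlas labels as placeholders.
It is a documented stand-in, not a published supplementary mapping; real
analyses replace the `atlas_label` column with their own parcellation labels
(many-to-one mappings allowed). Strengths aggregate onto homologs by
summation, because streamline counts are extensive quantities. Joint ranks
are computed over the full 3-seed × 27-homolog table at once; Spearman
correlations of fingerprints across species are unaffected by this (ranks
are presentational), and the cross-species p-values are Bonferroni-corrected
for the three seeds.

Tracer concordance (`tracer_concordance()`) validates a seed's tractography
vector against directed tracer strengths: bidirectional entries are averaged
(tractography is direction-blind), tracer regions map onto atlas regions by
a caller-supplied table with summation, unmappable regions are dropped, and
concordance is Spearman over the shared regions. A flag skips the averaging
for seeds whose tracer strengths exist in one direction only.

## Graph-theoretical stage

The tool-use subnetwork spans 10 nodes: TE, AIP, LIP, VIP, PMv/F5, PMd,
pre-SMA, MST, MT, FST. Each subject's subnetwork is normalized to total
strength 1 (cross-species comparability), then thresholded at sparsities
$s \in \{0.05, 0.10, \ldots, 0.5\}$, keeping the $\lceil s\,n(n-1)/2\rceil$
strongest edges *with their weights* (no binarization). Ties at the cut
break by weight then label pair; `ceiling` guarantees at least
$\lceil 0.05 \cdot 45 \rceil = 3$ edges at the sparsest level on 10 nodes.

The four nodal metrics use the standard weighted forms (the toolbox
tradition describes them only verbally, so the formulas are the contract
here, enforced by brute-force oracle tests):

* $Dc_i$ — node strength $\sum_j w_{ij}$ (a binary-degree variant is
  available behind a switch; strength is the default consistent with a
  weighted-network analysis).
* $Cp_i = \sum_{j \ne h} (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3} /
  [k_i(k_i-1)]$ with weights scaled by the network maximum and $k_i$ the
  binary degree; $k_i < 2 \Rightarrow 0$.
* $Eg_i = \frac{1}{n-1}\sum_{j\ne i} 1/d_{ij}$ on shortest paths with edge
  lengths $1/w$; unreachable pairs contribute 0, keeping fragmented
  thresholded networks finite.
* $Eloc_i$ — global efficiency of the subgraph induced by $i$'s neighbors
  with $i$ removed; fewer than two neighbors $\Rightarrow 0$.

Each node-metric curve over the sweep is summarized by its trapezoidal AUC
(`metric_auc()`); the rectangle rule was the other candidate and trapezoid
was pinned as the standard quadrature for a curve summary.

## The synthetic generator

The generator defines the study conditions under which the pipeline is
exercised:

* **ROI connectomes** (`generate_roi_connectomes()`): latent seed-to-target
  strengths come from a Gaussian copula with log-normal marginals. The
  normal-score correlation is set to $2\sin(\pi\rho_s/6)$ — the exact
  inverse of the normal-copula Spearman — so empirical rank correlations
  converge to `target_pattern_correlation` as the region count grows.
  Perfect targets ($\rho_s = \pm 1$) are implemented as exact column copies
  rather than left to floating-point round-off. Strengths are positive and
  right-skewed (log-normal, `sdlog = 1`), like streamline counts. Subject
  matrices multiply the latent values by symmetric log-normal noise
  (`subject_noise_sd`, default 0.3) and by the region-pair mean volume, so
  node-size normalization exactly recovers the latent scale at zero noise.
* **Voxel profiles** (`generate_voxel_profiles()`): expected counts are a
  deterministic radial intensity field times a seed-specific dorso-ventral
  band weight $\mathrm{logit}^{-1}(g(t-l))\cdot\mathrm{logit}^{-1}(g(u-t))$
  with bands dorsal/middle/ventral for MST/MT/FST along grid axis 3. At
  $g=0$ all three bands collapse to the same constant (human-like identical
  profiles); at large $g$ they approach disjoint indicator bands
  (macaque-like location dependence). Counts are Poisson draws, giving
  integer visitation counts with presence/absence variability where rates
  are low. Tissue masks split grid axis 1 into a white-matter half and a
  gray-matter half — a deliberate abstraction with no anatomical geometry.
* **Tracer tables** (`generate_tracer_table()`): two directed entries per
  region, each truth times independent log-normal noise.

The two species conditions are `human_like_config()` (gradient 0, target
correlation 0.9) and `macaque_like_config()` (gradient 30, target 0.2);
30 subjects each, 80 target regions, a 12×12×12 grid and a mean count scale
of 40 at the field's center. The grid and region counts are chosen so the
full two-species pipeline runs in seconds while leaving hundreds of voxels
per tissue class and a comfortably large rank vocabulary; 30 subjects gives
435 subject pairs per similarity set. The gradient slope 30 makes the
logistic transition width about a tenth of the dorso-ventral extent —
sharply banded but not degenerate; correlations 0.9 vs 0.2 encode "highly
similar" vs "weakly similar" fingerprints.

Each generator consumes the configuration seed plus a fixed offset, so the
same configuration regenerates bit-identical data, and the voxel and ROI
arms are independent given the seed. Note that two conditions sharing one
`rng_seed` share underlying normal draws; give each species its own seed (as
the analysis scripts do) when independence across conditions matters.

**What passing tests do and do not show.** The synthetic data reproduce the
*structural* features the pipeline depends on — multi-subject count volumes
with a dominance gradient, positive skewed connectome weights with
controllable inter-seed rank correlation, directed tracer noise — but not
cortical geometry, spatial autocorrelation of tractography error,
distance-dependent streamline attrition, gyral bias, or inter-regional
volume structure. Green tests certify the pipeline's arithmetic and its
recovery behavior under the stated noise model, not conclusions about real
brains. In particular, the two synthetic species are drawn independently, so
the cross-species fingerprint correlation has expected value 0 here — the
common-space stage is exercised as a negative control, and the positive
cross-species structure a real study observes must come from the data, not
the machinery.

## Numerical choices and degenerate inputs

* Spearman p-values use the asymptotic approximation (`exact = FALSE`),
  tolerating ties; Bonferroni caps adjusted p at 1.
* Dice and overlap fractions on empty inputs return flagged `NA`/`NaN` with
  a warning rather than silently returning 0.
* The copula correlation matrix is validated symmetric, unit-diagonal, and
  PSD (eigenvalue tolerance $-10^{-8}$); its square root uses the symmetric
  eigendecomposition, which is exact for singular perfect-correlation
  targets where a Cholesky factor is numerically unstable.
* All tie-breaks (target ranking, sparsity cut) are lexicographic by label,
  making every table byte-reproducible under a fixed seed.

## Limitations

* The shipped homology table is a placeholder mapping; cross-species claims
  require the user's own validated atlas-to-homolog table.
* The MPM dominance rule's three-seed generalization, tie handling, and
  zero handling are pinned choices documented above; other readings would
  relabel a small boundary population of voxels.
* Group-comparison statistics (repeated-measures ANOVAs and their
  nonparametric variants) are out of scope by design: the pipeline emits
  tidy per-subject tables ready for any stats package, and only a plain
  two-sample t-test is used in the synthetic species contrast.
* Graph metrics are nodal only; whole-network summaries (small-worldness,
  modularity) are not provided.
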