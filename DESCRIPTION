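Package: mtplusconn
Title: Cross-Species Structural Connectivity of MT+ Subregions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for comparing the structural connectivity of the MT+
    complex subregions (MST, MT, FST) between primate species from
    probabilistic-tractography outputs. Implements voxel-level profile
    binarization, group probabilistic maps, a modified maximum-probability-map
    dominance classification of white-matter voxels, pairwise and third-order
    Dice overlap coefficients, ROI-level connectome normalization and
    similarity analyses with Fisher z transformation, common-space comparison
    over homologous cortical regions, tracer-tractography concordance, and
    weighted nodal graph metrics (clustering, degree centrality, local and
    nodal efficiency) with sparsity-threshold sweeps and area-under-curve
    summaries. Ships a synthetic-data generator that emulates multi-subject
    seed-wise streamline count volumes and ROI connectomes with controllable
    inter-seed pattern correlation, so the full pipeline is testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
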