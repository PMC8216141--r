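Package: trabmech
Title: Cyclic Tensile Characterization of Individual Trabeculae
Version: 0.1.0
Authors@R: person("Trabmech", "Maintainers", email = "maintainers@trabmech.org",
    role = c("aut", "cre"))
Description: Tools for characterizing the material behavior of individual
    trabeculae from cyclic tensile tests. Implements forward simulation and
    inverse identification of a two-layer elasto-visco-plastic rheological
    model (an elasto-plastic Prandtl layer with Voce-type exponential
    hardening in parallel with a visco-elastic Maxwell layer), segmentation
    and exponential fitting of cyclic stress-strain records, envelope-based
    apparent mechanical properties, voxel-level tissue mineral density (TMD)
    analytics on micro-CT volumes, a hierarchical synthetic-cohort generator
    for end-to-end pipeline validation, and the nonparametric statistical
    layer (Mann-Whitney, Kruskal-Wallis, Wilcoxon signed-rank, Spearman,
    Bonferroni, IQR outlier screening, power analysis, single-covariate
    ANCOVA, and inter- vs intradonor variance comparison).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
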