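Package: glymphr
Type: Package
Title: Glymphatic Function MRI Markers: DTI-ALPS and gBOLD-CSF Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes two diffusion and functional MRI markers of brain
    glymphatic function: the DTI-ALPS index (a ratio of diffusivities
    perpendicular versus parallel to the periventricular fibre tracts,
    computed from a log-linear diffusion tensor fit and spherical
    template-space regions of interest) and the gBOLD-CSF coupling
    strength (the lagged Pearson cross-correlation between the global
    gray-matter BOLD signal and the cerebrospinal-fluid inflow signal,
    with a random-pairing permutation null). Includes a synthetic-data
    module (DWI phantoms with known tensors, lag-coupled BOLD/CSF series,
    and cohort tables matched to published group summaries), the
    summary-statistic group-comparison layer (ANOVA, variance-gated
    two-sample t, chi-square, Kruskal-Wallis, Bonferroni, partial
    correlation), and ROC/DeLong diagnostic-model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    signal,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
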