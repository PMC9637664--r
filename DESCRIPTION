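Package: qdpmri
Title: Pulmonary Perfusion Quantification and Test-Retest Analysis for DCE-MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pulmonary perfusion from dynamic contrast-enhanced
    (DCE) MRI time series: subtraction imaging, automatic arterial input
    function detection, truncated singular value decomposition deconvolution
    to residue-function maps, pulmonary blood flow (PBF) and blood volume
    (PBV), and the perfusion defect percentage (QDP) obtained by two-threshold
    Otsu clustering of median-filtered Rmax maps with per-slice gravity
    adaptation. Includes a synthetic two-visit 4D phantom generator with known
    ground truth, exam- and frame-level quality control, lung segmentation by
    region growing, and the test-retest agreement statistics used to compare
    perfusion metrics (Bland-Altman limits of agreement, minimal important
    difference from repeated-measures ANOVA, Wilcoxon signed-rank, Spearman
    correlation, and the Pearson-Filon test for dependent correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
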