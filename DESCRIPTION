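Package: vagidyn
Title: Longitudinal Vaginal Microbiome Community Dynamics and Relative
    Abundance Difference Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal analysis of vaginal microbiome amplicon
    data anchored to the menstrual cycle. Classifies samples into
    Lactobacillus dominance and codominance community types, quantifies
    shifts of the dominant taxon within participants over time, computes
    per-participant relative abundance differences (RAD) between time
    points with Wilcoxon signed-rank tests and Benjamini-Yekutieli
    correction, estimates differential RADs between treatment arms with
    the Hodges-Lehmann estimator, provides alpha diversity (inverse
    Simpson, richness) and Bray-Curtis based metrics including a
    neighbour-distance-minimizing sample ordering, predicts the dominant
    Lactobacillus from a species-specific qPCR panel, and simulates
    synthetic two-arm cohorts with menstrual perturbation for method
    validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
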