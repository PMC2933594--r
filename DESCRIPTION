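Package: boolgate
Title: Boolean Regulatory-Gate Inference from Factorial Expression Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genes whose nutrient/light regulation depends on a
    transcription-factor genotype in balanced 2x2x2 factorial expression
    experiments. Provides per-gene three-way factorial ANOVA with plug-in
    false-discovery-rate calibration, genotype-dependent gene-list extraction,
    Figure-of-Merit guided hierarchical clustering of expression profiles,
    per-cluster ANOVA, automated inference of two-input Boolean regulatory
    gates per genotype, and typing of genotype-driven de-regulation into
    attenuation, inversion, hidden and complex classes. Includes a synthetic
    data generator that plants clusters with known Boolean logic so every
    pipeline stage can be validated against ground truth, and a binomial
    over-representation test for functional annotation of gene lists.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
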