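Package: polyedit
Title: Liability-Threshold Predictions for Heritable Polygenic Genome Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts changes in disease prevalence and quantitative-trait
    means among genomes edited at ranked GWAS loci under an additive
    liability-threshold model. Reads genome-wide-significant summary
    statistics, converts log odds ratios to the liability scale, ranks loci
    by the product of effect size and undesirable-allele frequency, and
    produces prediction curves with between-genome uncertainty bands and
    gene-by-environment attenuation. Includes sensitivity analyses
    (misidentified causal variants, effect-size shrinkage, off-target
    mutational load, stabilizing selection), a Gini-index simulation of
    disease-risk inequality in mixed edited/unedited populations, and a
    synthetic GWAS summary-statistic generator for testing the full pipeline
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
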