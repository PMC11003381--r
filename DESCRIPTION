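Package: aquatrial
Title: Analysis of Fishmeal-Replacement Feeding Trials in Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of aquaculture feeding trials in which
    dietary fishmeal is replaced by blended alternative protein sources.
    Provides diet formulation on a protein-equivalent (isonitrogenous) basis,
    marker-based apparent digestibility coefficients (yttrium trioxide
    indicator), geometric-mean protein-quality indices (essential amino acid
    index and its digestible counterpart), standard growth and
    feed-utilization indices, broken-line (linear-plateau) dose-response
    regression for nutrient-requirement thresholds, one-way ANOVA with
    Duncan's multiple range test and compact letter display, reference-gene
    normalized qPCR relative expression, and a seeded synthetic-trial
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
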