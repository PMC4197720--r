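Package: pouchtrack
Title: Migration Metrics and Phenotype Scoring for Zebrafish Pharyngeal
    Pouch Morphogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of collective endodermal cell migration
    during zebrafish pharyngeal pouch formation. Computes per-cell track
    metrics (velocity, directional persistence, deviation-angle
    distributions) with a complete-track filter, scores pouch and
    ceratobranchial cartilage phenotypes on the field's 0/0.5/1/1.5
    rubrics, and compares genotype groups with one-tailed Welch t-tests,
    chi-square tests on angle distributions, Fisher's exact test, and
    Tukey-Kramer multiple comparisons. A seeded synthetic-data module
    (biased persistent random-walk tracks, genotype-parameterised
    phenotype records, pouch-formation timelines) makes every stage of
    the pipeline testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
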