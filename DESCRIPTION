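Package: culturopt
Title: Optimization of Culture-Condition Panels for Culturomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing binary species-by-culture-condition
    incidence matrices from high-throughput culturing (culturomics)
    studies of the human gut microbiota. Ranks culture conditions by
    bacterial richness, selects minimal condition panels by greedy
    maximum coverage (with an exact small-instance set-cover oracle),
    partitions species among condition groups by inclusion-exclusion,
    contrasts supplemented versus unsupplemented condition arms with a
    Pearson chi-square test, cross-tabulates recovery atmosphere against
    oxygen phenotype, applies 16S rRNA identity thresholds for taxon
    novelty, and generates seeded synthetic incidence matrices with the
    statistical structure of a large stool culturomics survey.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
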