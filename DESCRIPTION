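Package: phytoactive
Title: Biochemometric Ranking of Bioactive Features in Botanical Extract Fractions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correlates high-resolution mass-spectrometry molecular-feature
    intensities across botanical extract fractions with bioassay readouts to
    rank candidate bioactive compounds. Implements two independent feature
    ranking statistics: the selectivity ratio computed from a partial least
    squares model via target projection, and an ensemble of bootstrap Elastic
    Net regressions yielding selection frequencies. Also builds molecular
    networks from MS/MS spectra with (modified) cosine similarity, maps
    per-fraction bioactivity onto network nodes, exports GraphML, and
    annotates features against a compound library within a ppm mass window.
    Includes a synthetic-data generator with known ground truth for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
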