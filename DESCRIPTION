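Package: textcal
Title: Caloric Scoring of Region-Labelled Text Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An instrument for gauging the "caloric content" of large,
    region-labelled text corpora such as geotagged social media. Food and
    physical-activity phrase lexicons (kcal per 100 g; metabolic equivalents
    converted to kcal per hour at a reference body mass) are matched against
    phrases extracted by serial text partitioning, a greedy segmentation
    driven by random-partition phrase frequencies and context-local
    likelihoods. Per-region caloric input, output, ratio and a tunable
    caloric difference are computed, inter-region differences are decomposed
    into per-phrase shift contributions, and the resulting indices are
    correlated against health and well-being indicator tables with
    Benjamini-Hochberg false-discovery-rate control. A synthetic-data module
    generates fixture lexicons, corpora with planted phrase-usage
    multinomials, and indicator tables with planted monotone links.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
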