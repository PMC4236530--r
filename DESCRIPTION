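Package: slklink
Title: Statistical Linkage Key (SLK-581) Record Linkage and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deterministic record linkage of administrative health
    data using the 14-character statistical linkage key SLK-581, and for
    evaluating SLK-based strategies against a reference probabilistic
    person grouping (a master linkage key). Includes construction and
    quality classification of SLK-581 keys, five linkage strategies
    (full probabilistic grouping, basic SLK, most-recent SLK, most-frequent
    SLK, and a two-stage any-match strategy), missed-link and false-positive
    evaluation, hospitalisation-before-death utilisation statistics, and a
    calibrated synthetic generator of hospital admission and death
    registration records with hidden ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
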