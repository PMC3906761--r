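Package: pharmaboost
Title: Drug-Safety Signal Detection by Combining Spontaneous Reports with
    Literature Co-Occurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-marketing pharmacovigilance signal detection from
    FAERS-style spontaneous report files. Extracts drug-side-effect pairs via
    dictionary-based named entity recognition (mapping trade names to generic
    names), builds report-level 2x2 contingency tables, ranks pairs with seven
    signals (frequency, PRR, RRR, ROR, phi coefficient, information component,
    and an external score table), boosts the score of pairs that also co-occur
    in a biomedical literature corpus at sentence or abstract level, and
    evaluates rankings against a drug-label gold standard with 11-point
    interpolated average precision. Includes a seedable synthetic generator of
    reports, literature corpus, lexicons and gold standard with planted causal
    pairs and indication confounding, so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stringi,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
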