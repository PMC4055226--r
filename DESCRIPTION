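Package: greysoft
Title: Fuzzy Soft Set Decision Making via Grey Relational Analysis and
    Dempster-Shafer Evidence Combination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-criteria decision making over fuzzy soft sets
    (labelled membership tables of alternatives by parameters). Implements a
    decision pipeline that scores each parameter's uncertainty by grey mean
    relational analysis, converts the column-normalised membership table into
    basic probability assignments discounted by that uncertainty, and fuses
    the per-parameter evidence with Dempster's rule to rank the alternatives.
    Also provides the mean potentiality baseline method built on level soft
    sets, a performance measure for comparing decision methods, fuzzy soft
    set algebra (subset test, AND-product, level soft sets), general
    Dempster-Shafer mass and belief functions, delimited-text I/O with
    significant-figure tracking, a seeded random fuzzy-soft-set generator,
    and a small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
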