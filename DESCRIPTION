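Package: loxcross
Title: Exact Mendelian Analysis of Cre-Lox Dual-Marker Transgene Crossing Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models transgene constructs that carry two fluorescent transformation
    markers embedded in interweaved but incompatible Lox site pairs, enumerates
    Cre-mediated recombination products exactly, and computes exact Mendelian
    offspring distributions for multi-generation crossing schemes used to create
    homozygous transgenic lines. Includes a crossing-plan runner for the
    F3-to-F7 zygosity-genotyping procedure (plus swapped-gender and X-linked
    variants), a seeded multinomial brood-score simulator, and the segregation
    statistics used to compare observed progeny counts against theoretical
    Mendelian ratios (one-sample t-tests, goodness-of-fit tests, insertion-number
    and homozygous-viability classification rules, and germline recombination
    efficiency estimation). All probabilities are exact rationals up to the point
    of display or sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
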