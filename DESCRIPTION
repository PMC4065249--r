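Package: cemapr
Title: Conditional Epistatic Miniarray Profile Analysis
Version: 0.1.0
Authors@R: person("cemapr", "maintainers", email = "cemapr@example.org",
    role = c("aut", "cre"))
Description: Analysis of conditional epistatic miniarray profile (cE-MAP)
    screens: replicate-level S-score tables measured under untreated and
    DNA-damaging conditions are reduced to differential interaction scores,
    standardized to Z-scores, and corrected for multiple testing with an
    empirical-null tail-area false discovery rate to call condition-specific
    genetic interactions. Includes profile-level Pearson correlation and
    hierarchical clustering, two-sample Kolmogorov-Smirnov distribution
    comparisons, conditional interaction network construction with
    shared/unique partitions and hypergeometric overlap tests, term
    enrichment against a screened-gene background, a synthetic-screen
    generator with planted ground truth, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
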