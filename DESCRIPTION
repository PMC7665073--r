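Package: algafeed
Title: Growth, Digestibility and Feed-Cost Analysis for Microalgae-Based Aquafeeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating fish-free aquafeed formulations in tilapia
    feeding trials: tank-level growth-performance metrics (weight gain, FCR,
    SGR, PER, survival) with one-way ANOVA and Tukey HSD compact letter
    displays, including ANOVA reconstruction from published mean/SE summary
    tables; pH-stat degree-of-hydrolysis calculations and in-vitro protein
    digestibility prediction; hedonic mixed-effects pricing of novel feed
    ingredients from commodity price panels; and feed-cost and economic
    conversion ratio estimation with bootstrap confidence intervals. Includes
    synthetic-data generators that invert each analysis stage for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    boot,
    lme4,
    lmerTest,
    tibble,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
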