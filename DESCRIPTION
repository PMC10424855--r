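Package: wgmcat
Title: Weighted Geometric Mean and von Kries Chromatic Adaptation Transforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Chromatic adaptation transforms in the CAT16 cone space: classic
    von Kries scaling, the D-factor linear transform (CAT16 configuration),
    the three-anchor vK20 model, and the weighted geometric mean (WGM) model
    whose incomplete-adaptation predictions curve along the Planckian and
    daylight loci. Includes Planckian-radiator colorimetry against the CIE
    1931 2-degree observer, the corresponding-color Delta u'v' evaluation
    protocol with JND scaling and one-way ANOVA model comparison, bounded
    fitting of the degree of adaptation and of the reference point's
    correlated color temperature, a seeded synthetic generator for achromatic
    matches and corresponding-color pairs, a delimited dataset format, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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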