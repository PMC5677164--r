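Package: trdcross
Title: Two-Locus Transmission Ratio Distortion in Experimental Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gamete-level models and estimators for transmission ratio
    distortion (TRD) at a pair of epistatically interacting loci, motivated
    by the hms1-hms2 hybrid sterility system of the monkeyflowers Mimulus
    guttatus and M. nasutus.  Provides the two-locus genotype/gamete algebra
    and Mendelian and random-union-of-gametes null expectations; a
    transmission model combining gametic incompatibility (sex-specific
    killing of one two-locus gamete class), drive-like overtransmission at
    one locus, and background-dependent zygotic lethality; estimation of
    transmitted gamete-class frequencies from backcross progeny and
    model-based expected genotype frequencies; Pearson chi-square
    goodness-of-fit and heterogeneity tests; flanking-marker genotype
    inference with recombinant filtering; and a multinomial crossing-design
    simulator with maximum-likelihood parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
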