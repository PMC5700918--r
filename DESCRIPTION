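Package: spodsim
Title: Larval Dispersal of Spodoptera frugiperda on Bt Cotton: Simulation
    and Bioassay Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying neonate dispersal and feeding behaviour of
    Spodoptera frugiperda (fall armyworm) on Bt and non-Bt cotton. Provides
    a stochastic lattice individual-based model of immature and adult female
    dynamics on landscapes contaminated with the opposite cotton variety,
    with crop-dependent larval dispersal kernels; a synthetic generator for
    factorial host-acceptance bioassays and video-tracking movement
    endpoints; and the accompanying statistical pipeline: quasi-binomial
    logistic regression of survival on exposure time, Box-Cox factorial
    ANOVA, Tukey-Kramer multiple comparisons with compact letter displays,
    correlation-matrix PCA with Kaiser retention, and average-linkage
    (UPGMA) clustering of treatments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
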