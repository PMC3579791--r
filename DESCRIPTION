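Package: macroils
Title: Coalescent Simulation Diagnostics for Mitochondrial-Nuclear
    Gene-Tree Conflict in Kangaroos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and testing toolkit for deciding whether incomplete
    lineage sorting or introgression better explains conflict between
    mitochondrial and nuclear gene trees, built around the macropodid
    (kangaroo and wallaby) case of the swamp wallaby and the black-gloved
    wallaby. Simulates gene genealogies under the multispecies coalescent on
    dated species trees, evolves nucleotide alignments under GTR-family
    models with discrete-gamma rate heterogeneity, estimates maximum
    likelihood gene trees (pruning likelihood, branch-length optimization,
    NNI search, full and RELL bootstrap, KH/SH topology tests, Fitch
    parsimony), and provides the downstream diagnostics: clade-support
    tallies across an effective-population-size grid, sum-of-squares fit to
    observed gene support, placement-frequency tests, a parametric-bootstrap
    homogeneity test, the incongruence length difference test, chi-squared
    base-composition tests, and species-tree inference by minimizing deep
    coalescences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
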