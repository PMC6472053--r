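Package: milknmr
Title: Simulation, Quantification and Chemometrics of 1H-NMR Milk Lipid Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proton NMR lipidomics of bovine milk. Simulates 1D 1H
    spectra of milk lipid extracts from known fatty-acid compositions
    (Lorentzian lineshapes, first-order multiplets, Ernst-angle steady-state
    relaxation weighting), integrates the diagnostic signal regions, and
    quantifies minor unsaturated fatty acids (alpha-linolenic, linoleic,
    conjugated linoleic acid isomers, caproleic) as mole percentages of acyl
    chains from integral ratios, including a terminal-double-bond-corrected
    total-unsaturation equation. A chemometrics layer provides methyl-sum
    (NorCont) normalization, Pareto scaling, PCA, NIPALS PLS-DA with VIP
    scores, segmented cross-validation, permutation validation, Fisher's
    exact test of class predictions, and Hotelling T2 outlier screening, for
    discriminating organic from conventional milk cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lhs,
    mixOmics,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
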