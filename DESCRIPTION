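Package: editisland
Title: Amplicon-Level A-to-I RNA Editing Island Analysis of PDE8A Intron 9
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of targeted amplicon deep sequencing of
    the A-to-I RNA editing island in intron 9 of human PDE8A. Provides a
    read simulator with subject-level Dirichlet overdispersion and
    replicate structure, per-position base counting with G-percentage
    editing quantification and strict site calling, per-read co-editing
    isoform enumeration, clinical severity filtering, Wilcoxon/Welch group
    comparisons with Benjamini-Hochberg correction, and a random-forest
    discriminator of suicide attempters versus controls with ROC/AUC
    reporting. Includes an end-to-end pipeline driver with a
    reproducibility manifest.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    pROC,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
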