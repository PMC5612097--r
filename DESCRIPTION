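Package: pepscreenr
Title: Peptide-Array Substrate Discovery and Coupled-Assay Kinetics for
    Transglutaminases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering enzyme substrate motifs on ultra-dense
    combinatorial peptide microarrays and validating them by coupled-assay
    kinetics. Designs 5-mer peptide libraries under forbidden-substring
    exclusion rules with an exact transfer-matrix counter, designs
    maturation and substitution-scan follow-up libraries, simulates array
    fluorescence signals with duplicate synthesis and surface-imperfection
    spike noise, filters replicates by the |(S1-S2)/(S1+S2)| concordance
    statistic, ranks peptides and quantifies cross-enzyme reactivity,
    simulates glutamate-dehydrogenase-coupled NADH depletion traces with
    their characteristic lag phase, extracts post-lag linear rates, and
    fits Michaelis-Menten parameters with derived catalytic constants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    generics,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stringr,
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
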