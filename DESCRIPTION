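Package: patgen
Title: Patent-Aware De Novo Molecular Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an indexed database of drug-related patented compounds
    from patent-compound tables (IPC/CPC A61K/A61P selection, OCR-structure
    exclusion, ChEMBL-style standardization, stereo-free InChIKey identity),
    provides three interchangeable exact-structure match engines (InChIKey
    text lookup, MHFP6 MinHash locality-sensitive hashing, Morgan fingerprint
    brute force) with a latency benchmark, curates SMILES training corpora,
    trains a gated-recurrent-unit SMILES language model, and generates
    molecules by Monte Carlo tree search steered by patent-membership reward
    functions. Includes an evaluation suite: validity, uniqueness,
    patent-match counting, maximum-similarity distributions, QED
    drug-likeness, UMAP chemical-space projection and analog reports.
    Standard cheminformatics primitives are computed by RDKit through a
    persistent Python worker process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on the PATH
Imports:
    DBI,
    RSQLite,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    processx,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    uwot
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
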