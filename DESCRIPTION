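Package: mrprep
Title: Prepare Predicted Protein Models for Molecular Replacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns deep-learning predicted protein models (AlphaFold2,
    RoseTTAFold, ESMFold and similar) into molecular-replacement search
    models. Detects the per-residue confidence metric stored in the B-factor
    column (pLDDT on the 0-100 or 0-1 scale, or an estimated r.m.s.d. in
    Angstroms), converts it to crystallographic B factors, prunes
    low-confidence residues and short disconnected segments, splits models
    into rigid domain-like units by Ward clustering of C-alpha coordinates or
    by community detection on the predicted-aligned-error (PAE) matrix, and
    scores candidate models by mean pLDDT and a coverage-weighted score.
    Includes a synthetic fixture generator with planted domain architecture
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
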