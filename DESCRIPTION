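Package: alamsa
Title: Conformational Ensemble Sampling by Alanine Mutagenesis of
    Multiple Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Drives AlphaFold2-class structure predictors toward alternate
    protein conformations by systematic in-silico alanine mutagenesis of the
    multiple sequence alignment (MSA). Scans a confidence-trimmed region of
    an initial predicted model with a sliding window, tabulates heavy-atom
    contacts of each window with the rest of the protein, and alanizes the
    contacting positions across every sequence of the a3m alignment (gaps
    exempt), producing one mutated MSA per window for re-folding. Downstream
    tools quality-filter the resulting model sets by score statistics,
    compute TM-scores, RMSD and per-residue fluctuations against reference
    structures, and map the ensemble onto its dominant conformational modes
    by principal component analysis with iterative outlier pruning. Includes
    a deterministic mock folding backend and synthetic-data generators
    (hinge-motion toy structures, a3m alignments, score tables) so the whole
    pipeline is testable without GPU inference or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
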