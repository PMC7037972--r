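Package: draftmap
Title: Proteogenomic Draft-Map Construction and Diagnostic-Ion Spectral Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building draft proteome maps of unannotated organisms
    from genome sequence and shotgun mass spectrometry data. Builds six-frame
    translated theoretical protein databases from genome FASTA (stop-to-stop
    open reading frames with deterministic identifiers and genome coordinates),
    deduplicates and subsets protein FASTA files, and back-maps proteins to
    chromosomes by exact match. Reduces MS/MS peak lists (MGF) to spectra that
    contain diagnostic fragment ions such as glycan oxonium ions and the
    acetyllysine immonium-derived ion, with an elemental-composition m/z
    calculator and per-ion reporting. Merges eggNOG-mapper functional
    annotations into annotated protein FASTA headers, and correlates protein
    abundances with small-molecule feature abundances across samples (Pearson
    and Spearman with p-values, peptide-group roll-up, significance flagging).
    Includes concatenation pooling plans for high-pH fractionation and seeded
    generators for fully synthetic test inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
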