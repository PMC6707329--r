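Package: lncpeptidome
Title: Discovery and Quantification of lncRNA-Encoded Polypeptides from
    Peptide-Level Mass-Spectrometry Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A proteogenomic workflow for detecting and quantifying
    polypeptides translated from long non-coding RNA (lncRNA) transcripts
    using peptide-level label-free quantification evidence. Builds a
    hypothetical lncRNA peptidome by three-frame translation and in-silico
    tryptic digestion, removes peptides matching the canonical proteome,
    groups transcripts sharing peptides, enforces a
    two-non-overlapping-unique-peptide reporting rule, aggregates peptide
    intensities into polypeptide abundances, classifies tissue/cell-line
    specificity and universal expression, and tests cancer-versus-normal and
    stage-wise differential abundance with an empirical-Bayes moderated
    t-statistic. Includes a synthetic-evidence generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    seqinr,
    ape
Config/testthat/edition: 3
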