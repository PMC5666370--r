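Package: venompep
Title: Venom Peptidome Prediction and Mass-Spectral Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts mature venom peptides from precursor sequences using
    explicit post-translational processing rules (signal-peptide removal,
    dipeptidyl-peptidase spacer cleavage, carboxypeptidase des-Lys trimming,
    C-terminal amidation from a glycine donor, and disulfide homodimer
    formation), computes exact elemental formulas and monoisotopic masses,
    and assigns deconvoluted LC-ESI-MS neutral masses and b/y fragment-ion
    spectra to the predicted candidates. Includes a ground-truthed synthetic
    venom simulator for end-to-end validation, read-count expression
    profiling, and readers/writers for FASTA, TSV/CSV mass lists and MGF
    peak lists. Designed around pilosulin-like peptides from ant venom
    glands but applicable to any linear peptide precursor with annotated
    processing sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
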