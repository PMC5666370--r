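#' Published pilosulin-like peptide reference tables
#'
#' Curated reference data for the six pilosulin-like peptides (PLP1-PLP6)
#' identified in the venom gland of the trap-jaw ant *Odontomachus
#' monticola*: the mature-form candidate table with published molecular
#' formulas, the LC-ESI-MS peak table of the crude venom, and the MS/MS
#' de-novo peptide table. Sequences, retention times, areas and observed
#' masses are published data and stored as-is; every theoretical mass is
#' recomputed at call time by the package's mass engine.
#'
#' Two internal inconsistencies of the published mature-form table are
#' preserved and flagged rather than silently resolved
#' (`formula_consistent == FALSE`):
#' * the PLP5 row pairs an amidated sequence with the formula and mass of
#'   its free acid (formula route 1837.071 Da vs amide sequence route
#'   1836.087 Da); its `mass_basis` is therefore `"formula"`, reproducing
#'   the published pairing while exposing the conflict;
#' * the PLP2 row prints a formula (H224) that disagrees with its own
#'   sequence and mass (H244); the sequence route is authoritative there
#'   (`mass_basis = "sequence"`).
#'
#' For PLP4 the single-cysteine monomer dimerizes through one disulfide
#' bond; the homodimer mass (2 x monomer - 2 H = 6331.625 Da) is the
#' published, matchable species.
#'
#' @return `plp_candidates()`: tibble with `candidate_id`, `derivative`,
#'   `parent_id`, `sequence`, `c_term`, `trimmed`, `multimer`,
#'   `formula_printed`, `mass_sequence`, `mass_formula`, `mass_basis`,
#'   `formula_consistent`, and `mass` (the value on the published basis).
#' @examples
#' plp_candidates()[, c("candidate_id", "mass")]
#' @export
plp_candidates <- function() {
  ref <- tibble::tibble(
    candidate_id = c(
      "PLP1", "PLP1-desK", "PLP1-GK",
      "PLP2", "PLP3", "PLP3-K",
      "PLP4-dimer", "PLP5", "PLP6"
    ),
    derivative = c(
      "PLP1", "PLP1", "PLP1", "PLP2", "PLP3", "PLP3",
      "PLP4", "PLP5", "PLP6"
    ),
    sequence = c(
      "GILDWGKKVMDWIKDKM",
      "GILDWGKKVMDWIKDKMG",
      "GILDWGKKVMDWIKDKMGK",
      "GWGSIFKTVGKMIAKAAVKAAPEAISAMASQNE",
      "KIKWGKIFKKGGKLIGKTALEAAANAAASEAISAMASQNE",
      "KIKWGKIFKKGGKLIGKTALEAAANAAASEAISAMASQNEK",
      "GVKELFGKAWGLVKKHLPKACGLLGYVKQ",
      "IWGALLGTLIPAITSAIQ",
      "IKGKKIMKNMGKAMKIAGKVAKAMAPIVVPLIVSAA"
    ),
    c_term = c(
      "amide", "free_acid", "free_acid", "free_acid", "free_acid",
      "free_acid", "free_acid", "amide", "amide"
    ),
    trimmed = c(
      "GK", "K", "none", "K", "K", "none", "none", "GK", "GK"
    ),
    multimer = c(
      "monomer", "monomer", "monomer", "monomer", "monomer", "monomer",
      "disulfide_homodimer", "monomer", "monomer"
    ),
    formula_printed = c(
      "C95H152N24O23S2",
      "C97H154N24O25S2",
      "C103H166N26O26S2",
      "C149H224N40O44S2",
      "C182H305N51O54S",
      "C188H317N53O55S",
      "C300H484N78O68S2",
      "C87H144N20O23",
      "C168H306N46O38S4"
    ),
    # published basis of the theoretical mass column: the sequence route
    # everywhere except PLP5, whose printed formula/mass pair corresponds
    # to the free acid of the printed (amidated) sequence
    mass_basis = c(
      "sequence", "sequence", "sequence", "sequence", "sequence",
      "sequence", "sequence", "formula", "sequence"
    )
  )
  ref$mass_sequence <- vapply(
    seq_len(nrow(ref)),
    function(i) peptide_mass(ref$sequence[i], c_term = ref$c_term[i],
                             multimer = ref$multimer[i]),
    numeric(1)
  )
  ref$mass_formula <- vapply(ref$formula_printed, formula_mass, numeric(1),
                             USE.NAMES = FALSE)
  ref$formula_consistent <- abs(ref$mass_sequence - ref$mass_formula) < 0.005
  ref$mass <- ifelse(ref$mass_basis == "formula",
                     ref$mass_formula, ref$mass_sequence)
  ref$parent_id <- ref$derivative
  ref
}

#' @rdname plp_candidates
#' @return `plp_peak_table()`: tibble of LC-ESI-MS peaks of the crude
#'   venom on a wide-pore C8 column — `peak`, `label`, `rt` (min), `area`
#'   (percent of total, `NA` where printed only as a bound), `mass`
#'   (observed neutral monoisotopic Da) and `candidate_id` (the published
#'   assignment; `NA` for peaks left unassigned).
#' @examples
#' plp_peak_table()
#' @export
plp_peak_table <- function() {
  tibble::tibble(
    peak = c("4", "5", "6", "7b", "7a", "8", "9", "10", "13", "14",
             "15", "16", "17", "18", "19b", "19a", "20", "21", "22"),
    label = c("Om3264", "Om4117", "Om3489", "Om4229", "Om3101", "Om4101",
              "Om3704", "Om4401", "Om6368", "Om6350", "Om6332", "Om3362",
              "Om3325", "Om2247", "Om2119", "Om2061", "Om1782", "Om1812",
              "Om1837"),
    rt = c(10.58, 11.04, 13.84, 14.45, 14.45, 15.04, 16.51, 17.51,
           23.07, 23.99, 24.62, 25.37, 26.94, 27.66, 29.26, 29.76,
           32.05, 33.62, 34.86),
    area = c(0.41, 0.25, 0.46, NA, NA, 12.94, 4.29, 0.26, 20.85, 5.27,
             5.42, 7.78, 6.97, 1.52, NA, 27.41, 1.08, 0.67, 3.65),
    mass = c(3263.957, 4117.238, 3488.881, 4229.334, 3100.615, 4101.244,
             3704.235, 4401.364, 6367.557, 6349.589, 6331.631, 3361.756,
             3324.856, 2247.188, 2119.094, 2061.089, 1782.019, 1812.030,
             1836.995),
    candidate_id = c(NA, NA, NA, "PLP3-K", NA, "PLP3", "PLP6", NA, NA,
                     NA, "PLP4-dimer", "PLP2", NA, "PLP1-GK", "PLP1-desK",
                     "PLP1", NA, NA, "PLP5")
  )
}

#' @rdname plp_candidates
#' @return `plp_msms_peptides()`: tibble of peptides sequenced de novo
#'   from MS/MS fractions of the C18 run — `fraction`, `rt`, `sequence`
#'   (L stands for Leu or Ile), `c_term`, `met_oxide` (1-based S-oxide
#'   position or `NA`), `mass` (observed), `derivative`. Truncated and
#'   intact forms of PLP1-PLP3.
#' @examples
#' plp_msms_peptides()
#' @export
plp_msms_peptides <- function() {
  tibble::tibble(
    fraction = c(9L, 11L, 11L, 12L, 12L, 12L, 13L, 14L, 14L, 15L, 16L),
    rt = c(8.15, 8.55, 8.75, 9.08, 9.21, 9.40, 9.54, 10.95, 11.08,
           11.86, 12.75),
    sequence = c(
      "KVMDWLKDKM", "VMDWLKDKM", "AAANAAASEALSAMASQNE", "GLLDWGK",
      "GWGSLFK", "GWGSLFKT", "GWGSLFKTVGKM", "GWGSLFKTVGKMLAKAAVK",
      "KTALEAAANAAASEALSAMASQNE", "GLLDWGKKVMDWLKDKM",
      "GLLDWGKKVMDWLKDKM"
    ),
    c_term = c("amide", "amide", "free_acid", "free_acid", "free_acid",
               "free_acid", "free_acid", "free_acid", "free_acid",
               "amide", "amide"),
    met_oxide = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, 17L, NA),
    mass = c(1291.677, 1163.582, 1776.795, 787.423, 793.412, 894.458,
             1309.685, 1991.142, 2319.098, 2077.083, 2061.090),
    derivative = c("PLP1", "PLP1", "PLP3", "PLP1", "PLP2", "PLP2",
                   "PLP2", "PLP2", "PLP3", "PLP1", "PLP1")
  )
}

#' Synthetic precursor scaffolds for the pilosulin-like peptides
#'
#' Full precursor nucleotide-level sequences of PLP1-PLP6 are not publicly
#' printed; only the mature regions (with their C-terminal extensions) are.
#' This accessor builds six SYNTHETIC precursor records for demonstration
#' and testing: each is an invented (but rule-conforming) signal peptide
#' and acidic X-P/X-A dipeptide-repeat spacer joined to the published
#' mature region. Candidate enumeration depends only on the mature region,
#' so these scaffolds exercise the full processing pipeline while carrying
#' real mature sequences. The same records ship as
#' `inst/extdata/plp_precursors_synthetic.{fasta,tsv}`.
#'
#' @return Tibble of precursor records (`id`, `sequence`, `signal_end`,
#'   `propeptide_end`, `source`).
#' @examples
#' plp_precursors()$id
#' @export
plp_precursors <- function() {
  signal <- "MKPSLLLALLFVAVLA"          # synthetic 16-residue signal
  spacer <- "EAEPEAEADAEP"              # synthetic 6-repeat acidic spacer
  mature <- c(
    PLP1 = "GILDWGKKVMDWIKDKMGK",
    PLP2 = "GWGSIFKTVGKMIAKAAVKAAPEAISAMASQNEK",
    PLP3 = "KIKWGKIFKKGGKLIGKTALEAAANAAASEAISAMASQNEK",
    PLP4 = "GVKELFGKAWGLVKKHLPKACGLLGYVKQ",
    PLP5 = "IWGALLGTLIPAITSAIQGK",
    PLP6 = "IKGKKIMKNMGKAMKIAGKVAKAMAPIVVPLIVSAAGK"
  )
  do.call(rbind, lapply(names(mature), function(id) {
    precursor_record(
      id = id,
      sequence = paste0(signal, spacer, mature[[id]]),
      signal_end = nchar(signal),
      propeptide_end = nchar(signal) + nchar(spacer),
      source = "synthetic scaffold + published mature region"
    )
  }))
}
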