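#' Precursor record
#'
#' A venom peptide precursor with its processing annotation: the full
#' translated sequence, the 0-based index at which the signal peptide ends
#' (signal peptidase site), and optionally the index at which the propeptide
#' spacer ends. Indices are 0-based half-open internally; human-readable
#' reports are 1-based.
#'
#' @param id Precursor identifier.
#' @param sequence Full precursor amino-acid sequence.
#' @param signal_end 0-based position after which the signal peptide ends
#'   (equivalently, the number of signal residues). Must be annotated:
#'   no signal-peptide predictor is bundled.
#' @param propeptide_end Optional 0-based end of the propeptide spacer; when
#'   `NA` the spacer boundary is found by [process_propeptide()].
#' @param source Optional nucleotide source id.
#' @return A one-row tibble of class `precursor_record` semantics (plain
#'   tibble; several records row-bind naturally).
#' @examples
#' precursor_record("p1", "MKLSALLVEAEPGWGSIFK", signal_end = 8)
#' @export
precursor_record <- function(id, sequence, signal_end,
                             propeptide_end = NA_integer_,
                             source = NA_character_) {
  sequence <- .check_sequence(sequence)
  signal_end <- as.integer(signal_end)
  propeptide_end <- as.integer(propeptide_end)
  n <- nchar(sequence)
  if (is.na(signal_end) || signal_end <= 0 || signal_end >= n) {
    stop(
      "precursor '", id, "': signal_end must satisfy 0 < signal_end < ",
      n, " (annotate the signal peptidase site; it is not predicted)",
      call. = FALSE
    )
  }
  if (!is.na(propeptide_end) &&
      (propeptide_end < signal_end || propeptide_end > n)) {
    stop("precursor '", id, "': propeptide_end must lie in [signal_end, ",
         n, "]", call. = FALSE)
  }
  tibble::tibble(
    id = as.character(id),
    sequence = sequence,
    signal_end = signal_end,
    propeptide_end = propeptide_end,
    source = as.character(source)
  )
}

#' Remove the signal peptide
#'
#' Returns the pro-peptide (spacer + mature region) that remains after
#' signal peptidase cleavage at the annotated site.
#'
#' @param precursor A one-row precursor tibble from [precursor_record()].
#' @return The pro-peptide sequence string.
#' @examples
#' p <- precursor_record("p1", "MKLSALLVEAEPGWGSIFK", signal_end = 8)
#' strip_signal(p)
#' @export
strip_signal <- function(precursor) {
  stopifnot(nrow(precursor) == 1)
  if (is.na(precursor$signal_end)) {
    stop("precursor '", precursor$id, "' has no annotated signal cleavage ",
         "site; provide signal_end in the annotation table", call. = FALSE)
  }
  substring(precursor$sequence, precursor$signal_end + 1L)
}

#' Dipeptidyl-peptidase processing of the propeptide spacer
#'
#' Models dipeptidyl peptidase 4, which trims the spacer as successive
#' dipeptides: it cleaves after proline and alanine, so X-P and X-A pairs
#' are removed from the N-terminus while the second residue of the leading
#' pair is P or A. Iteration stops at the first pair violating the rule;
#' what remains is the mature region. Zero removals is a valid outcome.
#'
#' @param pro_sequence Pro-peptide sequence (output of [strip_signal()]).
#' @return A list with `mature_start` (0-based offset of the mature region
#'   within `pro_sequence`), `mature` (the remaining sequence) and
#'   `dipeptides` (character vector of removed pairs, in order).
#' @examples
#' process_propeptide("EAEPDAGWGSIFK")
#' @export
process_propeptide <- function(pro_sequence) {
  pro_sequence <- .check_sequence(pro_sequence)
  removed <- character()
  offset <- 0L
  n <- nchar(pro_sequence)
  while (offset + 2L <= n) {
    second <- substring(pro_sequence, offset + 2L, offset + 2L)
    if (!second %in% c("P", "A")) break
    removed <- c(removed, substring(pro_sequence, offset + 1L, offset + 2L))
    offset <- offset + 2L
  }
  list(
    mature_start = offset,
    mature = substring(pro_sequence, offset + 1L),
    dipeptides = removed
  )
}

# assemble one candidate row with formula + mass computed by the mass engine
.candidate_row <- function(parent_id, sequence, c_term, trimmed, multimer,
                           provenance, residue_mods = list()) {
  f <- peptide_formula(sequence, c_term, residue_mods, multimer)
  tibble::tibble(
    parent_id = parent_id,
    sequence = sequence,
    c_term = c_term,
    trimmed = trimmed,
    multimer = multimer,
    provenance = provenance,
    formula = format_formula(f),
    mass = formula_mass(f)
  )
}

#' Enumerate mature peptide candidates for a precursor
#'
#' Applies the venom maturation rules to the mature region obtained after
#' [strip_signal()] and [process_propeptide()]:
#'
#' 1. the untrimmed mature region as a free acid;
#' 2. if it ends in glycine or glycine-lysine, the amidated form with the
#'    G / GK donor removed (amidating lyase after carboxypeptidase), plus —
#'    for a GK ending — the des-K free-acid intermediate still carrying the
#'    glycine donor;
#' 3. if it ends in lysine immediately preceded by glutamate (the E-K
#'    motif), the des-K free acid (carboxypeptidase); `des_k_any` relaxes
#'    this to any C-terminal K;
#' 4. if a monomeric form contains exactly one cysteine, its disulfide
#'    homodimer (two identical chains joined by one S-S bond). With more
#'    than one Cys the inter-chain topology is ambiguous and no dimer is
#'    generated (a warning is recorded).
#'
#' Amidation is only generated from a glycine donor; an amide without a
#' C-terminal G in the precursor is never emitted.
#'
#' @param precursor One-row tibble from [precursor_record()] (or a row of
#'   [read_precursors()] output).
#' @param amidation,des_k,dimer Logical rule toggles (all default `TRUE`).
#' @param des_k_any Relax des-K trimming from the E-K motif to any
#'   C-terminal lysine. Default `FALSE`.
#' @return Tibble of candidates: `parent_id`, `sequence`, `c_term`,
#'   `trimmed` (`none`/`K`/`GK`/`G`), `multimer`, `provenance`, `formula`
#'   (Hill text) and `mass` (monoisotopic Da). Deterministic and sorted by
#'   decreasing mass for stability.
#' @examples
#' p <- precursor_record("PLP1-like", "MKLSALLVEAEPGILDWGKKVMDWIKDKMGK",
#'                       signal_end = 8)
#' enumerate_mature_forms(p)
#' @export
enumerate_mature_forms <- function(precursor, amidation = TRUE,
                                   des_k = TRUE, dimer = TRUE,
                                   des_k_any = FALSE) {
  stopifnot(nrow(precursor) == 1)
  pro <- strip_signal(precursor)
  if (!is.na(precursor$propeptide_end)) {
    mature <- substring(precursor$sequence, precursor$propeptide_end + 1L)
    # sanity: the annotated boundary must be consistent with the repeat rule
    # only in that the mature region is non-empty
    if (!nzchar(mature)) {
      stop("precursor '", precursor$id, "': empty mature region",
           call. = FALSE)
    }
  } else {
    mature <- process_propeptide(pro)$mature
  }

  id <- precursor$id
  out <- .candidate_row(id, mature, "free_acid", "none", "monomer", "full")
  n <- nchar(mature)
  last1 <- substring(mature, n, n)
  last2 <- if (n >= 2) substring(mature, n - 1L, n) else ""

  if (amidation && last2 == "GK" && n >= 4) {
    out <- rbind(
      out,
      # carboxypeptidase intermediate: des-K, glycine donor still present
      .candidate_row(id, substring(mature, 1L, n - 1L), "free_acid", "K",
                     "monomer", "full"),
      # amidating lyase product: des-GK, amidated
      .candidate_row(id, substring(mature, 1L, n - 2L), "amide", "GK",
                     "monomer", "full")
    )
  } else if (amidation && last1 == "G" && n >= 3) {
    out <- rbind(
      out,
      .candidate_row(id, substring(mature, 1L, n - 1L), "amide", "G",
                     "monomer", "full")
    )
  } else if (des_k && last1 == "K" && n >= 3) {
    prev <- substring(mature, n - 1L, n - 1L)
    if (des_k_any || prev == "E") {
      out <- rbind(
        out,
        .candidate_row(id, substring(mature, 1L, n - 1L), "free_acid", "K",
                       "monomer", "full")
      )
    }
  }

  if (dimer) {
    n_cys <- vapply(
      strsplit(out$sequence, ""),
      function(x) sum(x == "C"),
      integer(1)
    )
    if (any(n_cys > 1)) {
      warning(
        "precursor '", id, "': >1 cysteine; disulfide homodimer not ",
        "generated (inter-chain topology ambiguous)",
        call. = FALSE
      )
    }
    monomers <- out[out$multimer == "monomer" & n_cys == 1L, , drop = FALSE]
    if (nrow(monomers) > 0) {
      dimers <- do.call(rbind, lapply(seq_len(nrow(monomers)), function(i) {
        .candidate_row(
          id, monomers$sequence[i], monomers$c_term[i], monomers$trimmed[i],
          "disulfide_homodimer", monomers$provenance[i]
        )
      }))
      out <- rbind(out, dimers)
    }
  }

  out <- unique(out)
  out[order(-out$mass, out$sequence), ]
}

#' Terminal-anchored truncation ladder of a candidate
#'
#' Venom peptidomes contain N- and C-terminally truncated forms of the full
#' mature peptides, whether from processing or in-venom proteolysis. This
#' emits every prefix (as a free acid: the C-terminal state is lost with
#' the C-terminus) and every suffix (inheriting the parent's C-terminal
#' state) of length >= `min_length`, with formula and mass, deduplicated by
#' (sequence, terminal state). Internal fragments are not generated.
#'
#' @param candidate One-row candidate tibble (monomeric) as produced by
#'   [enumerate_mature_forms()], or a list/row with `sequence`, `c_term`,
#'   `parent_id`.
#' @param min_length Minimum fragment length, >= 3 (default 5).
#' @return Tibble of candidates with `provenance` of `full`,
#'   `prefix-truncation` or `suffix-truncation`.
#' @examples
#' p <- precursor_record("PLP1-like", "MKLSALLVEAEPGILDWGKKVMDWIKDKMGK",
#'                       signal_end = 8)
#' forms <- enumerate_mature_forms(p)
#' ladder <- truncation_ladder(forms[forms$c_term == "amide", ])
#' nrow(ladder)
#' @export
truncation_ladder <- function(candidate, min_length = 5L) {
  stopifnot(nrow(candidate) == 1, min_length >= 3)
  if (candidate$multimer != "monomer") {
    stop("truncation ladder is defined for monomeric candidates only",
         call. = FALSE)
  }
  seqc <- candidate$sequence
  n <- nchar(seqc)
  id <- candidate$parent_id
  min_length <- as.integer(min_length)

  rows <- list(
    .candidate_row(id, seqc, candidate$c_term, candidate$trimmed,
                   "monomer", "full")
  )
  if (n > min_length) {
    for (len in seq(min_length, n - 1L)) {
      # prefix loses the C-terminus: always a free acid
      rows[[length(rows) + 1L]] <- .candidate_row(
        id, substring(seqc, 1L, len), "free_acid", "none", "monomer",
        "prefix-truncation"
      )
      # suffix keeps the C-terminus: inherits the parent state
      rows[[length(rows) + 1L]] <- .candidate_row(
        id, substring(seqc, n - len + 1L, n), candidate$c_term,
        candidate$trimmed, "monomer", "suffix-truncation"
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("sequence", "c_term")]), ]
  out[order(-out$mass, out$sequence), ]
}
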