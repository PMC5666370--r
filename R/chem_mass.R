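#' Peptide modification specifications
#'
#' A modification is a signed elemental delta plus a constraint on where it
#' may apply. Applying then reverting a modification restores the original
#' formula exactly (integer arithmetic).
#'
#' @param name Modification name.
#' @param gain,loss [elemental_formula()]s (or strings) added / removed.
#' @param constraint One of `"N-term"`, `"C-term"`, `"residue"`,
#'   `"whole-molecule"`.
#' @param residues For `constraint = "residue"`, the residue letters the
#'   modification is valid on.
#' @return A `modification_spec` list.
#' @examples
#' modifications()$met_oxide
#' @export
modification_spec <- function(name, gain = elemental_formula(),
                              loss = elemental_formula(),
                              constraint = c("residue", "N-term", "C-term",
                                             "whole-molecule"),
                              residues = character()) {
  constraint <- match.arg(constraint)
  structure(
    list(
      name = name,
      gain = as_elemental_formula(gain),
      loss = as_elemental_formula(loss),
      constraint = constraint,
      residues = residues
    ),
    class = "modification_spec"
  )
}

#' Built-in modifications
#'
#' * `met_oxide` — methionine S-oxide, +O on a Met residue (+15.99491 Da).
#' * `amidation` — C-terminal amide replacing the free acid: net -O +N +H
#'   (-0.98402 Da). Usually requested through the `c_term` argument of
#'   [peptide_formula()] rather than applied directly.
#'
#' @return Named list of [modification_spec()]s.
#' @export
modifications <- function() {
  list(
    met_oxide = modification_spec(
      "met_oxide",
      gain = "O",
      constraint = "residue",
      residues = "M"
    ),
    amidation = modification_spec(
      "amidation",
      gain = "NH",
      loss = "O",
      constraint = "C-term"
    )
  )
}

.resolve_mod <- function(mod) {
  if (inherits(mod, "modification_spec")) return(mod)
  if (is.character(mod) && length(mod) == 1) {
    reg <- modifications()
    if (!mod %in% names(reg)) {
      stop("unknown modification '", mod, "'; built-ins: ",
           paste(names(reg), collapse = ", "), call. = FALSE)
    }
    return(reg[[mod]])
  }
  stop("residue_mods entries need a modification_spec or built-in name",
       call. = FALSE)
}

.check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence)) stop("empty peptide sequence", call. = FALSE)
  letters_seen <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters_seen, names(.residue_formulas))
  if (length(bad) > 0) {
    stop(
      "sequence contains non-standard residue letter(s): ",
      paste(unique(bad), collapse = ", "),
      " (B, Z, X, U, O are rejected, not approximated)",
      call. = FALSE
    )
  }
  sequence
}

#' Elemental formula of a peptide
#'
#' Builds the exact formula of a peptide from its residue composition and
#' terminal/modification state:
#' * free acid = sum of residue formulas + H2O;
#' * C-terminal amide = free acid - O + N + H;
#' * methionine S-oxide adds one O at a Met position;
#' * disulfide homodimer = 2 x monomer - 2 H (one S-S bond between two
#'   identical single-cysteine chains).
#'
#' @param sequence One-letter residue string (20 standard letters;
#'   Leu and Ile are interchangeable in mass).
#' @param c_term `"free_acid"` or `"amide"`.
#' @param residue_mods List of residue-level modifications, each a
#'   `list(pos = <1-based position>, mod = <name or modification_spec>)`.
#' @param multimer `"monomer"` or `"disulfide_homodimer"`. The homodimer
#'   requires at least one Cys; `c_term` and `residue_mods` describe each
#'   chain and are applied per chain.
#' @return An [elemental_formula()].
#' @examples
#' format_formula(peptide_formula("GILDWGKKVMDWIKDKM", c_term = "amide"))
#' format_formula(peptide_formula("G"))
#' @export
peptide_formula <- function(sequence,
                            c_term = c("free_acid", "amide"),
                            residue_mods = list(),
                            multimer = c("monomer", "disulfide_homodimer")) {
  c_term <- match.arg(c_term)
  multimer <- match.arg(multimer)
  sequence <- .check_sequence(sequence)
  letters_seen <- strsplit(sequence, "")[[1]]

  f <- elemental_formula(c(H = 2L, O = 1L))  # terminal water
  composition <- table(letters_seen)
  for (res in names(composition)) {
    f <- f + elemental_formula(.residue_formulas[[res]]) * composition[[res]]
  }

  if (c_term == "amide") {
    amid <- modifications()$amidation
    f <- f + amid$gain - amid$loss
  }

  if (length(residue_mods) > 0) {
    for (entry in residue_mods) {
      if (!is.list(entry) || is.null(entry$pos)) {
        stop("each residue_mods entry must be list(pos = , mod = )",
             call. = FALSE)
      }
      pos <- as.integer(entry$pos)
      if (pos < 1 || pos > length(letters_seen)) {
        stop("modification position ", pos, " outside sequence of length ",
             length(letters_seen), call. = FALSE)
      }
      mod <- .resolve_mod(entry$mod)
      if (mod$constraint == "residue" &&
          !(letters_seen[pos] %in% mod$residues)) {
        stop(
          "modification '", mod$name, "' requires residue ",
          paste(mod$residues, collapse = "/"), " but position ", pos,
          " is ", letters_seen[pos], call. = FALSE
        )
      }
      f <- f + mod$gain - mod$loss
    }
  }

  if (multimer == "disulfide_homodimer") {
    if (!grepl("C", sequence, fixed = TRUE)) {
      stop("disulfide homodimer requires at least one cysteine",
           call. = FALSE)
    }
    f <- f * 2L - elemental_formula(c(H = 2L))
  }

  f
}

#' Monoisotopic mass of a peptide
#'
#' `formula_mass(peptide_formula(...))` with the same arguments. Diagnostic
#' deltas: amidation shifts the mass by -0.98402 Da versus the free acid,
#' Met S-oxide by +15.99491 Da, and a disulfide homodimer weighs
#' 2 x monomer - 2.01565 Da.
#'
#' @inheritParams peptide_formula
#' @param kind `"monoisotopic"` (default) or `"average"`.
#' @return Mass in Da at full precision; round to 3 decimals for reports.
#' @examples
#' round(peptide_mass("GWGSLFK"), 3)
#' round(peptide_mass("GILDWGKKVMDWIKDKM", c_term = "amide"), 3)
#' @export
peptide_mass <- function(sequence,
                         c_term = c("free_acid", "amide"),
                         residue_mods = list(),
                         multimer = c("monomer", "disulfide_homodimer"),
                         kind = c("monoisotopic", "average")) {
  formula_mass(
    peptide_formula(sequence, c_term, residue_mods, multimer),
    kind = match.arg(kind)
  )
}
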