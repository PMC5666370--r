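#' ESI charge-state arithmetic
#'
#' Electrospray produces multiply protonated ions; the neutral monoisotopic
#' mass M relates to the observed mass-to-charge ratio by
#' `mz = (M + z * proton) / z`. `deconvolute()` inverts that relation;
#' `charge_project()` applies it. The proton mass (1.00727646 Da) is used,
#' not the hydrogen-atom mass: protonation adds no electron.
#'
#' @param mz Observed m/z (must exceed the proton mass).
#' @param z Positive integer charge.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' deconvolute(1031.5520, 2)
#' charge_project(2061.0895, 3)
#' @export
deconvolute <- function(mz, z) {
  z <- as.integer(z)
  if (any(z <= 0)) stop("charge must be a positive integer", call. = FALSE)
  if (any(mz <= PROTON_MASS)) {
    stop("m/z must exceed the proton mass", call. = FALSE)
  }
  z * (mz - PROTON_MASS)
}

#' @rdname deconvolute
#' @param mass Neutral monoisotopic mass in Da.
#' @export
charge_project <- function(mass, z) {
  z <- as.integer(z)
  if (any(z <= 0)) stop("charge must be a positive integer", call. = FALSE)
  (mass + z * PROTON_MASS) / z
}

#' Observed-mass table constructor
#'
#' @param mass Neutral monoisotopic masses (Da), > 0.
#' @param rt Retention times (min); `NA` allowed.
#' @param area Relative areas in percent, within \[0, 100\]; `NA` allowed.
#' @param label Source labels (peak ids); autogenerated when missing.
#' @return Tibble with columns `label`, `mass`, `rt`, `area`.
#' @export
observed_masses <- function(mass, rt = NA_real_, area = NA_real_,
                            label = NULL) {
  stopifnot(all(mass > 0))
  if (any(!is.na(area) & (area < 0 | area > 100))) {
    stop("area must lie in [0, 100] percent", call. = FALSE)
  }
  if (is.null(label)) label <- paste0("Om", round(mass))
  tibble::tibble(
    label = as.character(label),
    mass = as.numeric(mass),
    rt = as.numeric(rt),
    area = as.numeric(area)
  )
}

#' Assign observed neutral masses to peptide candidates
#'
#' Each observed mass is matched against the candidate theoretical masses
#' within a tolerance of `max(tol_ppm * mass * 1e-6, tol_da)`: a ppm
#' criterion with an absolute floor, because small observed-vs-theoretical
#' gaps in Da exceed a few ppm for short peptides. When `loose_da` is
#' given, masses failing the strict tolerance but within `loose_da` are
#' still assigned and flagged `loose = TRUE` so borderline identifications
#' remain visible rather than silently dropped or silently accepted.
#'
#' Status per observed mass: `unique` (one candidate within tolerance, or a
#' clear nearest), `ambiguous` (several within tolerance; all are listed,
#' sorted by absolute error, ties broken by fewer modifications implied —
#' here by candidate mass — then lexicographic sequence), or `unassigned`.
#'
#' @param observed Tibble from [observed_masses()] (columns `label`,
#'   `mass`, optionally `rt`, `area`).
#' @param candidates Candidate tibble with at least `sequence` and `mass`
#'   (e.g. from [enumerate_mature_forms()]); an optional `candidate_id`
#'   column overrides the derived id.
#' @param tol_ppm Strict relative tolerance in ppm (default 10).
#' @param tol_da Absolute floor in Da (default 0.02).
#' @param loose_da Optional loose absolute tolerance in Da (e.g. 0.1);
#'   `NULL` disables the loose pass.
#' @return Tibble with one row per (observed, candidate-in-tolerance) pair
#'   plus one row per unassigned observation: `label`, `mass`, `rt`,
#'   `candidate_id`, `sequence`, `theoretical`, `error_da`, `error_ppm`,
#'   `status`, `loose`. Sorted by retention time, then label.
#' @examples
#' obs <- observed_masses(2061.089, rt = 29.76)
#' cand <- tibble::tibble(sequence = "GILDWGKKVMDWIKDKM",
#'                        mass = peptide_mass("GILDWGKKVMDWIKDKM", "amide"))
#' match_masses(obs, cand)
#' @export
match_masses <- function(observed, candidates, tol_ppm = 10,
                         tol_da = 0.02, loose_da = NULL) {
  stopifnot(tol_ppm > 0, tol_da > 0)
  if (!is.null(loose_da) && loose_da < tol_da) {
    stop("loose_da must be >= tol_da", call. = FALSE)
  }
  if (nrow(candidates) == 0) {
    warning("empty candidate list: all observed masses unassigned",
            call. = FALSE)
  }
  if (!"rt" %in% names(observed)) observed$rt <- NA_real_
  if (!"candidate_id" %in% names(candidates) && nrow(candidates) > 0) {
    state <- if ("c_term" %in% names(candidates)) {
      candidates$c_term
    } else {
      "free_acid"
    }
    mult <- if ("multimer" %in% names(candidates)) {
      candidates$multimer
    } else {
      "monomer"
    }
    candidates$candidate_id <- paste0(
      candidates$sequence,
      ifelse(state == "amide", "-NH2", ""),
      ifelse(mult == "disulfide_homodimer", "-dimer", "")
    )
  }

  empty_row <- function(o) {
    tibble::tibble(
      label = o$label, mass = o$mass, rt = o$rt,
      candidate_id = NA_character_, sequence = NA_character_,
      theoretical = NA_real_, error_da = NA_real_, error_ppm = NA_real_,
      status = "unassigned", loose = NA
    )
  }

  if (nrow(observed) == 0) {
    return(tibble::tibble(
      label = character(), mass = numeric(), rt = numeric(),
      candidate_id = character(), sequence = character(),
      theoretical = numeric(), error_da = numeric(),
      error_ppm = numeric(), status = character(), loose = logical()
    ))
  }

  rows <- lapply(seq_len(nrow(observed)), function(i) {
    o <- observed[i, ]
    if (nrow(candidates) == 0) return(empty_row(o))
    strict_tol <- max(tol_ppm * o$mass * 1e-6, tol_da)
    accept_tol <- if (is.null(loose_da)) strict_tol else max(strict_tol, loose_da)
    err <- o$mass - candidates$mass
    hit <- abs(err) <= accept_tol
    if (!any(hit)) return(empty_row(o))
    idx <- which(hit)
    # deterministic ordering: |error|, then candidate mass, then sequence
    idx <- idx[order(abs(err[idx]), candidates$mass[idx],
                     candidates$sequence[idx])]
    status <- if (length(idx) == 1) "unique" else "ambiguous"
    tibble::tibble(
      label = o$label, mass = o$mass, rt = o$rt,
      candidate_id = candidates$candidate_id[idx],
      sequence = candidates$sequence[idx],
      theoretical = candidates$mass[idx],
      error_da = err[idx],
      error_ppm = err[idx] / candidates$mass[idx] * 1e6,
      status = status,
      loose = abs(err[idx]) > strict_tol
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$rt, out$label, method = "radix", na.last = TRUE), ]
}

#' Theoretical b/y fragment ions of a peptide
#'
#' Singly to `max_charge`-fold protonated b and y ions of a monomeric
#' peptide: `b_i` is the first i residues plus a proton; `y_i` is the last
#' i residues plus the C-terminal group (H2O for a free acid, NH3 for an
#' amide — only y ions carry the C-terminal state) plus a proton. Higher
#' charges via `(M_frag + z * proton) / z`.
#'
#' @param sequence Peptide sequence.
#' @param c_term `"free_acid"` or `"amide"` (affects y ions only).
#' @param ion_types Subset of `c("b", "y")`.
#' @param max_charge Highest fragment charge state (default 1).
#' @return Tibble with `ion` (label like `"b2"` or `"y3^2+"`), `series`,
#'   `index`, `charge`, `mz`, sorted by m/z. A length-n peptide yields
#'   `2 * (n - 1)` b+y ions per charge state.
#' @examples
#' fragment_ions("GWGSLFK")
#' @export
fragment_ions <- function(sequence, c_term = c("free_acid", "amide"),
                          ion_types = c("b", "y"), max_charge = 1L) {
  c_term <- match.arg(c_term)
  ion_types <- match.arg(ion_types, several.ok = TRUE)
  sequence <- .check_sequence(sequence)
  stopifnot(max_charge >= 1)
  letters_seen <- strsplit(sequence, "")[[1]]
  n <- length(letters_seen)
  if (n < 2) stop("fragment ions need at least 2 residues", call. = FALSE)
  res_mass <- vapply(
    letters_seen,
    function(a) formula_mass(elemental_formula(.residue_formulas[[a]])),
    numeric(1),
    USE.NAMES = FALSE
  )
  am <- atomic_masses("monoisotopic")
  c_term_group <- if (c_term == "amide") {
    am[["N"]] + 3 * am[["H"]]          # -NH2 terminus as NH3 on the y ion
  } else {
    2 * am[["H"]] + am[["O"]]          # water
  }

  rows <- list()
  for (z in seq_len(max_charge)) {
    zl <- if (z == 1) "" else paste0("^", z, "+")
    if ("b" %in% ion_types) {
      neutral <- cumsum(res_mass)[seq_len(n - 1L)]   # b_i residue sum
      rows[[length(rows) + 1L]] <- tibble::tibble(
        ion = paste0("b", seq_len(n - 1L), zl),
        series = "b", index = seq_len(n - 1L), charge = z,
        mz = (neutral + z * PROTON_MASS) / z
      )
    }
    if ("y" %in% ion_types) {
      neutral <- cumsum(rev(res_mass))[seq_len(n - 1L)] + c_term_group
      rows[[length(rows) + 1L]] <- tibble::tibble(
        ion = paste0("y", seq_len(n - 1L), zl),
        series = "y", index = seq_len(n - 1L), charge = z,
        mz = (neutral + z * PROTON_MASS) / z
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$mz), ]
}

#' MS/MS peak list
#'
#' @param mz Fragment m/z values (> 0).
#' @param intensity Intensities (>= 0); defaults to 1.
#' @param precursor_mz,precursor_z Precursor ion m/z and charge.
#' @param rt Retention time (min).
#' @param title Spectrum title.
#' @return A `peak_list` object.
#' @export
peak_list <- function(mz, intensity = NULL, precursor_mz = NA_real_,
                      precursor_z = NA_integer_, rt = NA_real_,
                      title = "spectrum") {
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  stopifnot(length(mz) == length(intensity), all(mz > 0),
            all(intensity >= 0))
  structure(
    list(
      mz = as.numeric(mz), intensity = as.numeric(intensity),
      precursor_mz = precursor_mz,
      precursor_z = as.integer(precursor_z),
      rt = rt, title = title
    ),
    class = "peak_list"
  )
}

#' @export
print.peak_list <- function(x, ...) {
  cat("<peak_list> ", x$title, ": ", length(x$mz), " peaks",
      if (!is.na(x$precursor_mz)) {
        paste0(", precursor ", round(x$precursor_mz, 4),
               if (!is.na(x$precursor_z)) paste0(" (", x$precursor_z, "+)"))
      },
      "\n", sep = "")
  invisible(x)
}

#' Score a candidate against an MS/MS peak list
#'
#' Counts the theoretical b/y ions of the candidate that are matched by at
#' least one peak within `frag_tol` Da. The score is the matched fraction
#' (matched / total theoretical ions); it is a plain coverage count, not a
#' probabilistic score.
#'
#' @param peaklist A [peak_list()].
#' @param candidate One-row candidate tibble (monomeric) with `sequence`
#'   and `c_term`, or a plain list with those fields.
#' @param frag_tol Fragment tolerance in Da (default 0.02).
#' @param max_charge Fragment charge states considered (default 1).
#' @return Tibble: `candidate_id`, `matched`, `total`, `fraction`,
#'   `empty_peaklist` flag.
#' @examples
#' ions <- fragment_ions("GWGSLFK")
#' pl <- peak_list(ions$mz)
#' score_msms(pl, list(sequence = "GWGSLFK", c_term = "free_acid"))
#' @export
score_msms <- function(peaklist, candidate, frag_tol = 0.02,
                       max_charge = 1L) {
  stopifnot(inherits(peaklist, "peak_list"), frag_tol > 0)
  if (!is.null(candidate$multimer) &&
      any(candidate$multimer == "disulfide_homodimer")) {
    stop("the b/y fragment model is monomer-only", call. = FALSE)
  }
  seqc <- candidate$sequence[[1]]
  ct <- if (is.null(candidate$c_term)) "free_acid" else candidate$c_term[[1]]
  theo <- fragment_ions(seqc, c_term = ct, max_charge = max_charge)
  empty <- length(peaklist$mz) == 0
  if (empty) {
    warning("empty peak list: zero matches", call. = FALSE)
    matched <- 0L
  } else {
    matched <- sum(vapply(
      theo$mz,
      function(m) any(abs(peaklist$mz - m) <= frag_tol),
      logical(1)
    ))
  }
  cid <- if (!is.null(candidate$candidate_id)) {
    candidate$candidate_id[[1]]
  } else {
    paste0(seqc, if (ct == "amide") "-NH2" else "")
  }
  tibble::tibble(
    candidate_id = cid,
    matched = as.integer(matched),
    total = nrow(theo),
    fraction = if (nrow(theo) > 0) matched / nrow(theo) else 0,
    empty_peaklist = empty
  )
}

#' Virtual fractionation: retention-time binning
#'
#' Slices an observed-mass table (or any table with an `rt` column) into
#' retention-time bins, emulating the construction of an on-line mass
#' fingerprint from a total ion current trace.
#'
#' @param observed Tibble with an `rt` column (minutes).
#' @param bin_width Bin width in minutes (default 0.5).
#' @return The input with an integer `fraction` column (1-based bin index
#'   from the earliest retention time); rows with `NA` rt get `NA`.
#' @export
virtual_fractions <- function(observed, bin_width = 0.5) {
  stopifnot(bin_width > 0, "rt" %in% names(observed))
  rt0 <- suppressWarnings(min(observed$rt, na.rm = TRUE))
  observed$fraction <- if (is.finite(rt0)) {
    as.integer(floor((observed$rt - rt0) / bin_width)) + 1L
  } else {
    NA_integer_
  }
  observed
}
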