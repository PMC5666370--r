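#' Specification for a synthetic venom
#'
#' Parameters of the ground-truthed simulator. Defaults emulate a small
#' pilosulin-like venom-gland peptidome: a hydrophobic signal peptide, a
#' propeptide spacer of acidic X-P / X-A dipeptide repeats (P or A at every
#' second position with D/E between them), and a basic amphiphilic mature
#' region ending in one of the C-terminal processing motifs. Mass lists are
#' perturbed with ppm-scale Gaussian noise matching a well-calibrated
#' orbitrap (1-3 ppm) and contaminated with decoy masses placed away from
#' any true mass so that recovery is well-defined.
#'
#' @param n_precursors Number of precursors (default 6).
#' @param spacer_repeats Integer vector to sample the number of spacer
#'   dipeptide repeats from (default 2:6).
#' @param mature_length Range of mature-region lengths before the motif
#'   (default c(15, 40)).
#' @param motif_probs Named probabilities over C-terminal motifs
#'   `c(GK=, G=, EK=, cys=, plain=)`; must sum to 1. `cys` places a single
#'   cysteine in the mature region (homodimer-forming), `plain` adds no
#'   motif.
#' @param mass_noise_ppm Gaussian noise scale for observed masses in ppm
#'   (default 3, the calibration precision of a maintained orbitrap).
#' @param n_decoys Number of decoy masses (default 5).
#' @param dropout MS/MS fragment-ion dropout rate in \[0, 1) (default 0).
#' @param seed Integer seed; fixes all outputs bit-for-bit.
#' @return A `synthetic_venom_spec` list.
#' @export
synthetic_venom_spec <- function(n_precursors = 6L,
                                 spacer_repeats = 2:6,
                                 mature_length = c(15L, 40L),
                                 motif_probs = c(GK = 0.3, G = 0.1,
                                                 EK = 0.3, cys = 0.15,
                                                 plain = 0.15),
                                 mass_noise_ppm = 3,
                                 n_decoys = 5L,
                                 dropout = 0,
                                 seed = 1L) {
  stopifnot(
    n_precursors >= 1,
    all(spacer_repeats >= 0),
    length(mature_length) == 2, mature_length[1] >= 5,
    mature_length[2] >= mature_length[1],
    mass_noise_ppm >= 0, n_decoys >= 0, dropout >= 0, dropout < 1
  )
  motif_names <- c("GK", "G", "EK", "cys", "plain")
  if (!setequal(names(motif_probs), motif_names)) {
    stop("motif_probs needs exactly the names ",
         paste(motif_names, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(motif_probs) - 1) > 1e-9) {
    stop("motif_probs must sum to 1", call. = FALSE)
  }
  structure(
    list(
      n_precursors = as.integer(n_precursors),
      spacer_repeats = as.integer(spacer_repeats),
      mature_length = as.integer(mature_length),
      motif_probs = motif_probs[motif_names],
      mass_noise_ppm = mass_noise_ppm,
      n_decoys = as.integer(n_decoys),
      dropout = dropout,
      seed = as.integer(seed)
    ),
    class = "synthetic_venom_spec"
  )
}

# residue pool enriched in K, A, G, I, L: basic amphiphilic mature regions
# resembling pilosulins, giving realistic mass collisions
.mature_pool <- c(
  K = 0.16, A = 0.14, G = 0.10, I = 0.10, L = 0.10,
  V = 0.06, S = 0.06, M = 0.05, T = 0.04, F = 0.04,
  W = 0.03, N = 0.03, Q = 0.03, E = 0.03, D = 0.02, P = 0.01
)

.sample_residues <- function(n, pool = .mature_pool) {
  paste(
    sample(names(pool), n, replace = TRUE, prob = pool),
    collapse = ""
  )
}

.random_signal <- function() {
  # Met start then a hydrophobic stretch
  core <- sample(c("L", "A", "V", "I", "F", "S", "C"), 14,
                 replace = TRUE,
                 prob = c(0.3, 0.2, 0.15, 0.15, 0.1, 0.05, 0.05))
  paste0("MK", paste(core, collapse = ""), "A")
}

.random_spacer <- function(n_repeats) {
  if (n_repeats == 0) return("")
  first <- sample(c("D", "E"), n_repeats, replace = TRUE)
  second <- sample(c("P", "A"), n_repeats, replace = TRUE)
  paste0(first, second, collapse = "")
}

#' Generate ground-truthed synthetic precursors
#'
#' Each precursor is signal peptide + spacer of X-P/X-A dipeptide repeats
#' (X from D/E) + a mature region carrying its assigned C-terminal motif.
#' The ground truth records exactly the mature candidates the rule engine
#' must emit, computed by running [enumerate_mature_forms()] on the known
#' architecture — so a round trip through precursor processing at zero
#' noise must agree exactly.
#'
#' @param spec A [synthetic_venom_spec()].
#' @return List with `precursors` (tibble: `id`, `sequence`, `signal_end`,
#'   `propeptide_end`, `source`, plus generator fields `motif`, `mature`)
#'   and `truth` (candidate tibble as from [enumerate_mature_forms()]).
#' @examples
#' sv <- generate_precursors(synthetic_venom_spec(n_precursors = 2, seed = 7))
#' sv$precursors$id
#' @export
generate_precursors <- function(spec) {
  stopifnot(inherits(spec, "synthetic_venom_spec"))
  set.seed(spec$seed)
  motifs <- sample(
    names(spec$motif_probs), spec$n_precursors,
    replace = TRUE, prob = spec$motif_probs
  )
  rows <- vector("list", spec$n_precursors)
  for (i in seq_len(spec$n_precursors)) {
    signal <- .random_signal()
    spacer <- .random_spacer(sample(spec$spacer_repeats, 1))
    len <- sample(seq(spec$mature_length[1], spec$mature_length[2]), 1)
    pool <- .mature_pool
    core <- .sample_residues(len, pool)
    # mature region may not itself start like a spacer dipeptide, or the
    # dipeptidyl peptidase would eat into it; fix the 2nd residue
    while (substring(core, 2, 2) %in% c("P", "A")) {
      substring(core, 2, 2) <- sample(
        setdiff(names(pool), c("P", "A")), 1,
        prob = pool[setdiff(names(pool), c("P", "A"))] /
          sum(pool[setdiff(names(pool), c("P", "A"))])
      )
    }
    core <- gsub("C", "S", core)  # cysteines only by explicit motif
    motif <- motifs[i]
    if (motif == "cys") {
      pos <- sample(seq(3, nchar(core) - 2), 1)
      substring(core, pos, pos) <- "C"
      mature <- core
    } else if (motif == "EK") {
      mature <- paste0(substring(core, 1, nchar(core) - 2), "EK")
    } else if (motif == "GK") {
      mature <- paste0(core, "GK")
    } else if (motif == "G") {
      mature <- paste0(core, "G")
    } else {
      mature <- core
    }
    rows[[i]] <- tibble::tibble(
      id = sprintf("syn%02d", i),
      sequence = paste0(signal, spacer, mature),
      signal_end = nchar(signal),
      propeptide_end = nchar(signal) + nchar(spacer),
      source = NA_character_,
      motif = motif,
      mature = mature
    )
  }
  precursors <- do.call(rbind, rows)
  truth <- do.call(rbind, lapply(seq_len(nrow(precursors)), function(i) {
    enumerate_mature_forms(precursors[i, c(
      "id", "sequence", "signal_end", "propeptide_end", "source"
    )])
  }))
  list(precursors = precursors, truth = truth)
}

#' Generate observed masses and MS/MS peak lists from ground truth
#'
#' True candidate masses are perturbed with Gaussian noise of
#' `mass_noise_ppm` ppm; decoy masses are drawn uniformly over the true
#' mass range but rejected until they lie more than 5x the noise scale
#' (and at least 0.5 Da) away from every true mass, so that decoys are
#' identifiable at the default matching tolerance. MS/MS peak lists are
#' built from the theoretical b/y ions of monomeric candidates with the
#' specified dropout.
#'
#' @param truth Candidate tibble (the `truth` element of
#'   [generate_precursors()]).
#' @param spec The same [synthetic_venom_spec()].
#' @return List: `observed` (tibble `label`, `mass`, `rt`, `area`),
#'   `assignments` (ground-truth tibble `label`, `candidate_id`,
#'   `true_mass`, `is_decoy`), `peaklists` (named list of [peak_list()]s
#'   for monomeric candidates).
#' @export
generate_observed <- function(truth, spec) {
  stopifnot(inherits(spec, "synthetic_venom_spec"), nrow(truth) > 0)
  set.seed(spec$seed + 1L)
  cid <- paste0(
    truth$sequence,
    ifelse(truth$c_term == "amide", "-NH2", ""),
    ifelse(truth$multimer == "disulfide_homodimer", "-dimer", "")
  )
  noise <- stats::rnorm(nrow(truth), 0,
                        pmax(spec$mass_noise_ppm, 1e-12)) *
    truth$mass * 1e-6
  if (spec$mass_noise_ppm == 0) noise <- 0
  obs_mass <- truth$mass + noise

  n_dec <- spec$n_decoys
  decoys <- numeric(0)
  if (n_dec > 0) {
    lo <- min(truth$mass) * 0.8
    hi <- max(truth$mass) * 1.2
    guard <- pmax(5 * spec$mass_noise_ppm * 1e-6 * hi, 0.5)
    while (length(decoys) < n_dec) {
      m <- stats::runif(1, lo, hi)
      if (all(abs(m - truth$mass) > guard)) decoys <- c(decoys, m)
    }
  }

  all_mass <- c(obs_mass, decoys)
  labels <- c(
    sprintf("obs%03d", seq_along(obs_mass)),
    if (n_dec > 0) sprintf("dec%03d", seq_len(n_dec))
  )
  rt <- round(stats::runif(length(all_mass), 5, 35), 2)
  area <- round(100 * stats::runif(length(all_mass)) /
                  sum(stats::runif(length(all_mass))), 3)
  observed <- observed_masses(all_mass, rt = rt, area = NA, label = labels)
  observed$area <- pmin(area, 100)

  assignments <- tibble::tibble(
    label = labels,
    candidate_id = c(cid, rep(NA_character_, n_dec)),
    true_mass = c(truth$mass, rep(NA_real_, n_dec)),
    is_decoy = c(rep(FALSE, length(obs_mass)), rep(TRUE, n_dec))
  )

  monomers <- which(truth$multimer == "monomer")
  peaklists <- lapply(monomers, function(i) {
    ions <- fragment_ions(truth$sequence[i], c_term = truth$c_term[i])
    keep <- stats::runif(nrow(ions)) >= spec$dropout
    if (!any(keep)) keep[sample(nrow(ions), 1)] <- TRUE
    peak_list(
      mz = ions$mz[keep],
      intensity = stats::runif(sum(keep), 1e3, 1e6),
      precursor_mz = charge_project(truth$mass[i], 2L),
      precursor_z = 2L,
      rt = NA_real_,
      title = cid[i]
    )
  })
  names(peaklists) <- cid[monomers]

  list(observed = observed, assignments = assignments,
       peaklists = peaklists)
}
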