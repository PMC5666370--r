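---
title: "Predicting and matching a venom peptidome: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and matching a venom peptidome: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venompep)
```

## The problem

Ant venom glands express peptide toxins as precursors: a hydrophobic
signal peptide, an acidic propeptide spacer, and the mature peptide,
sometimes with a short C-terminal extension that is removed or converted
during maturation. A venom-gland transcriptome therefore predicts
*precursors*, while LC-ESI-MS of the venom observes *mature peptides*.
Connecting the two requires an explicit model of post-translational
processing and exact mass arithmetic: a mature pilosulin-like peptide can
differ from its precursor-encoded region by a dipeptide-repeat spacer,
one or two C-terminal residues, an amide group (0.98 Da), or
dimerization. venompep implements that bridge as a small, testable rule
engine plus an exact mass engine, and matches the predictions against
deconvoluted neutral masses and b/y fragment spectra.

## Mass model

Peptide masses are monoisotopic, built from integer elemental formulas:

* residue formulas of the 20 standard amino acids (Leu/Ile identical);
* free acid = sum of residue formulas + H~2~O;
* C-terminal amide = free acid − O + N + H (−0.98402 Da);
* methionine S-oxide = +O (+15.99491 Da) at an annotated Met;
* disulfide homodimer = 2 × monomer − 2 H (−2.01565 Da).

Atomic masses are fixed constants (C = 12 exactly, H = 1.0078250319,
N = 14.0030740052, O = 15.9949146221, S = 31.97207069; proton
1.00727646). With these constants every published theoretical mass the
package targets is reproduced at the 3-decimal precision in which such
tables are printed; all arithmetic is kept at full double precision and
rounded only for display. Formula arithmetic is integer and checked —
subtracting below zero atoms is an error, not a clamp — so applying and
reverting a modification restores the original formula bit-for-bit.
Average masses are available as a secondary mode but nothing in the
matching pipeline uses them. Nonstandard letters (B, Z, X, U, O) are
rejected rather than approximated; ambiguous residues would silently
corrupt exact masses.

Two independent routes to a peptide mass exist in the code base —
formula accumulation and residue-mass summation — and the test suite
requires them to agree to 10^-6^ Da on random sequences.

## Maturation rules

Processing is modelled as an ordered rule set acting on an annotated
precursor:

1. **Signal peptidase.** The cleavage site is a *required annotation*.
   No predictor is bundled: prediction quality would silently bound
   everything downstream, and curated sites are available whenever the
   precursor is worth analyzing.
2. **Dipeptidyl peptidase 4.** The spacer is removed as successive
   X-P / X-A dipeptides from the N-terminus; iteration stops at the
   first leading pair whose second residue is not P or A. Zero removals
   is valid. The removed dipeptides concatenate with the remainder to
   restore the input — an invariant the tests exercise.
3. **Carboxypeptidase / amidating lyase.** A mature region ending in
   G-K yields three forms: the untrimmed free acid, the des-K free acid
   (carboxypeptidase intermediate, glycine donor still present), and
   the des-GK amide (the glycine donor is consumed by amidating lyase).
   A bare terminal G yields the amide only. Amidation is *never*
   generated without a glycine donor.
4. **Des-K trimming.** A C-terminal K immediately preceded by E (the
   E-K motif) is removable as a free acid. A configuration flag
   (`des_k_any`) relaxes this to any terminal K for exploratory use;
   the default stays strict because the motif is what the biology
   supports.
5. **Disulfide homodimer.** A monomeric form with exactly one cysteine
   also yields its homodimer (2 M − 2 H). With two or more cysteines
   the inter-chain topology is ambiguous, so no dimer is generated and
   a warning records the decision. Heterodimers between different
   peptides are not generated at all.

Truncation ladders model in-venom proteolysis and incomplete
processing: all prefixes (free acids — the C-terminus is lost with the
fragment) and suffixes (inheriting the parent's C-terminal state) down
to `min_length = 5`. Five leaves a margin of two below the shortest
peptidome fragment the package's reference tables contain (7 residues)
without flooding the candidate space with tiny ambiguous fragments.
Ladders are terminal-anchored only; every reference peptidome fragment
is a prefix or suffix of a full form, and internal fragments would grow
the search space quadratically for no demonstrated benefit.

All coordinates are 0-based half-open internally and 1-based only in
human-readable output.

## Matching model

ESI deconvolution is exact arithmetic: M = z × (m/z − 1.00727646),
using the proton mass (protonation adds no electron). The round trip
through charge projection is tested to 10^-9^ Da.

Observed-vs-theoretical matching uses a ppm tolerance with an absolute
floor: accept when |Δ| ≤ max(10 ppm × M, 0.02 Da). The floor matters
for short peptides, where instrument accuracy in Da translates to more
ppm than on large peptides. A second, explicitly labelled *loose* tier
(0.1 Da) captures borderline identifications — assignments in that tier
carry `loose = TRUE` and their error, so they are visible rather than
either discarded or silently accepted. One reference peak (the PLP5
row, 0.076 Da from its published theoretical mass) is only reachable
through this tier, which is exactly the behaviour the tier exists for.

When several candidates fall inside tolerance the assignment is
`ambiguous` and all of them are reported sorted by |error| (ties broken
by candidate mass, then sequence, for determinism). Peaks with no
candidate in tolerance stay `unassigned`; the matcher never forces a
fit. Shrinking the tolerance can only reduce the number of assigned
peaks — a monotonicity property under test. Retention time is carried
through for reporting and binning ("virtual fractionation") but is
never a matching feature; predicted retention is out of scope.

MS/MS confirmation uses b/y ions: b~i~ = sum of the first i residues +
proton; y~i~ = sum of the last i residues + the C-terminal group + proton,
where only y ions see the amide state. The score is the matched
fraction of theoretical ions at a 0.02 Da fragment tolerance — a plain
coverage count. No probabilistic model is claimed: with a handful of
candidate peptides per venom, coverage plus mass agreement is the
decision-relevant quantity, and a calibrated E-value would suggest
precision the model does not have. The fragment model is monomer-only;
fragmenting a disulfide dimer produces inter-chain species the simple
b/y model cannot represent, so it is an error, not an approximation.

## Reference data and its inconsistencies

The package ships curated tables for the six pilosulin-like peptides of
the trap-jaw ant *Odontomachus monticola*: the mature-form candidates
with their published molecular formulas, the LC-MS peak table, and the
MS/MS-sequenced peptidome fragments. Published sequences and observed
masses are stored as data; every theoretical value is recomputed at
call time by the mass engine.

Two rows of the published candidate table are internally inconsistent,
and the package preserves both conflicts instead of resolving them
silently:

* the PLP5 row pairs an amidated sequence with the formula and mass of
  its *free acid* (1837.071 Da; the amide computes to 1836.087 Da).
  The table reproduces the published pairing (`mass_basis =
  "formula"`) and flags the row `formula_consistent = FALSE`;
* the PLP2 row prints a formula whose hydrogen count disagrees with its
  own sequence and mass; the sequence route is authoritative there and
  the row is flagged.

A related note: the PLP4 monomer mass computes to 3166.820 Da with this
constant set, 0.01 Da above one published mention; the homodimer value
6331.625 Da — the species actually observable in venom — is reproduced
exactly and is what the package treats as authoritative.

Full precursor sequences for these peptides (signal + spacer) are not
publicly printed. The bundled precursor records therefore join the
published mature regions to a *synthetic* signal peptide and spacer,
clearly labelled as such; enumeration depends only on the mature
region, so the pipeline is exercised end-to-end on real mature
sequences.

## Synthetic venoms

The generator builds ground-truthed inputs for every stage: precursors
(signal + X-P/X-A spacer + mature region with an assigned C-terminal
motif), observed mass lists, and MGF peak lists. Defaults: 6
precursors, 2–6 spacer repeats, mature lengths 15–40, motif mix 30%
GK / 10% G / 30% EK / 15% single-Cys / 15% plain, 3 ppm Gaussian mass
noise, 5 decoys, no fragment dropout. The noise scale is the
calibration precision of a maintained orbitrap (1–3 ppm); the residue
pool for mature regions is enriched in K, A, G, I, L to resemble basic
amphiphilic pilosulins, which makes mass collisions realistically
possible rather than vanishingly rare. Decoys are rejected until they
lie more than 5 × the noise scale (at least 0.5 Da) from every true
mass, so recovery rates measure the matcher, not decoy luck. A fixed
seed makes every output bit-for-bit reproducible.

What the simulation does *not* emulate: isotope envelopes and their
deconvolution, chromatographic peak shape, co-elution and ion
suppression, real spacer length variation beyond the dipeptide rule,
and in-venom proteolysis beyond terminal truncation. A 100% recovery
on synthetic venoms at zero noise therefore validates the bookkeeping
and the rule engine, not instrument-level robustness; the 3 ppm /
decoy condition validates tolerance handling under calibrated noise
only.

The simulation-based tests run 20 seeds of the default venom (about
15 true masses plus 5 decoys per seed) and one zero-noise seed; the
property tests use 1000 random sequences for the terminal deltas and
500 masses across 4 charge states for the deconvolution round trip.
These sizes give stable pass/fail behaviour at negligible cost.

## Degenerate inputs and numerical choices

* Empty formulas have mass 0; unknown element symbols and nonstandard
  residue letters raise errors naming the offender.
* `signal_end` must lie strictly inside the precursor; a zero-length
  signal is rejected.
* An empty candidate list leaves every mass unassigned with a warning;
  an empty observed list produces an empty, well-typed assignment
  table; an empty MS/MS peak list scores zero with a flag.
* Masses are compared on full doubles; the 3-decimal rounding applied
  in reports and the acceptance values matches the precision of the
  published tables.
* `match_masses` output ordering (retention time, then label) and the
  candidate tie-break chain make every pipeline product deterministic;
  the simulator is deterministic conditional on its seed.

## Limitations

Beyond the simulator limits above: signal cleavage sites must be
supplied, not predicted; the rule set covers the maturation chemistry
of linear Aculeata-type peptides (spacer dipeptides, G/GK amidation,
E-K des-K, single-Cys homodimers) and would need extension for, e.g.,
multi-bridge knottins; and MS/MS scoring is confirmation, not de novo
sequencing.
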