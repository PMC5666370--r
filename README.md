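# venompep

Venom peptidome prediction and mass-spectral matching in R.

Venom-gland transcriptomes predict peptide toxin *precursors*; LC-ESI-MS
of the venom observes *mature peptides*. venompep bridges the two for
linear Aculeata-type venom peptides (pilosulins, melittin and their
relatives): it applies explicit post-translational processing rules to
annotated precursors, computes exact elemental formulas and monoisotopic
masses, and assigns deconvoluted neutral masses and b/y fragment spectra
to the predicted candidates. It is written for venomics groups who have
a precursor list and a deconvoluted mass list and want the assignment
step to be explicit, auditable and testable.

## The model

A precursor is signal peptide + propeptide spacer + mature region.
Maturation is modelled as:

* **signal peptidase** cleavage at an annotated site (required input,
  never predicted);
* **dipeptidyl peptidase 4** removal of the spacer as successive X-P /
  X-A dipeptides;
* **carboxypeptidase + amidating lyase** at the C-terminus: a …GK
  ending yields the untrimmed free acid, the des-K intermediate and the
  des-GK amide (−0.98402 Da vs. the free acid); …EK loses its lysine;
* **disulfide homodimer** formation for single-cysteine peptides
  (2 M − 2 H = 2 M − 2.01565 Da);
* terminal-anchored **truncation ladders** for in-venom proteolysis.

Masses are exact monoisotopic sums over integer elemental formulas
(free acid = Σ residues + H₂O), and matching accepts an observed
neutral mass M against a candidate when |Δ| ≤ max(10 ppm × M, 0.02 Da),
with a labelled loose tier (0.1 Da) for borderline identifications.
Deconvolution follows M = z × (m/z − 1.00727646).

## Worked example

The package ships the six pilosulin-like peptide precursors of the
trap-jaw ant *Odontomachus monticola* (published mature regions on a
synthetic signal/spacer scaffold) and the venom's LC-ESI-MS peak table.
Enumerate mature forms and match the observed masses:

```r
library(venompep)

p <- plp_precursors()
forms <- do.call(rbind, lapply(seq_len(nrow(p)),
                               function(i) enumerate_mature_forms(p[i, ])))
forms[forms$parent_id == "PLP1",
      c("sequence", "c_term", "trimmed", "multimer", "mass")]
#>   sequence            c_term    trimmed multimer  mass
#> 1 GILDWGKKVMDWIKDKMGK free_acid none    monomer  2247.
#> 2 GILDWGKKVMDWIKDKMG  free_acid K       monomer  2119.
#> 3 GILDWGKKVMDWIKDKM   amide     GK      monomer  2061.

obs <- plp_peak_table()
asn <- match_masses(observed_masses(obs$mass, rt = obs$rt, label = obs$label),
                    plp_candidates(), loose_da = 0.1)
asn[asn$status != "unassigned",
    c("label", "mass", "candidate_id", "theoretical", "error_da", "loose")]
#>   label     mass candidate_id theoretical error_da loose
#>  Om4229 4229.334       PLP3-K    4229.336   -0.002 FALSE
#>  Om4101 4101.244         PLP3    4101.241    0.003 FALSE
#>  Om3704 3704.235         PLP6    3704.231    0.004 FALSE
#>  Om6332 6331.631   PLP4-dimer    6331.625    0.006 FALSE
#>  Om3362 3361.756         PLP2    3361.753    0.003 FALSE
#>  Om2247 2247.188      PLP1-GK    2247.191   -0.003 FALSE
#>  Om2119 2119.094    PLP1-desK    2119.096   -0.002 FALSE
#>  Om2061 2061.089         PLP1    2061.090   -0.001 FALSE
#>  Om1837 1836.995         PLP5    1837.071   -0.076  TRUE
```

Reading the output: the intact amidated PLP1 (2061.090 Da theoretical)
is observed 1 mDa off; its unprocessed (…GK) and intermediate (…G)
forms co-occur in the venom; PLP4 is matched as its disulfide homodimer;
and PLP5 only fits the loose 0.1 Da tier (`loose = TRUE`) — its
published theoretical mass corresponds to the free acid of an amidated
sequence, an inconsistency the candidate table flags rather than hides
(see `?plp_candidates` and the methods vignette). Ten further peaks
(e.g. Om6368, Om6350) have no candidate and stay unassigned.

Other entry points: `truncation_ladder()` for truncated peptidome
forms, `fragment_ions()` / `score_msms()` for b/y confirmation,
`expression_profile()` for read-count percentages,
`synthetic_venom_spec()` / `generate_precursors()` /
`generate_observed()` for ground-truthed simulations, and a thin
command-line front-end in `inst/cli/venompep` (subcommands `process`,
`match`, `fragments`, `profile`, `simulate`).

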