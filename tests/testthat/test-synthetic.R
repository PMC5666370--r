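test_that("the generator is bit-for-bit deterministic per seed", {
  spec <- synthetic_venom_spec(n_precursors = 4, seed = 99)
  a <- generate_precursors(spec)
  b <- generate_precursors(spec)
  expect_identical(a, b)
  oa <- generate_observed(a$truth, spec)
  ob <- generate_observed(b$truth, spec)
  expect_identical(oa, ob)
  # a different seed gives different sequences
  c2 <- generate_precursors(synthetic_venom_spec(n_precursors = 4,
                                                 seed = 100))
  expect_false(identical(a$precursors$sequence, c2$precursors$sequence))
})

test_that("generated precursors round-trip through the processing rules", {
  spec <- synthetic_venom_spec(n_precursors = 8, seed = 3)
  sv <- generate_precursors(spec)
  for (i in seq_len(nrow(sv$precursors))) {
    p <- sv$precursors[i, ]
    # spacer removal alone must recover the generator's mature region
    pro <- strip_signal(p[, c("id", "sequence", "signal_end",
                              "propeptide_end", "source")])
    expect_identical(process_propeptide(pro)$mature, p$mature)
    # and its dipeptide count equals the generated repeat count
    n_rep <- (p$propeptide_end - p$signal_end) / 2
    expect_identical(length(process_propeptide(pro)$dipeptides),
                     as.integer(n_rep))
  }
  # rule-engine output on the emitted records equals the stored truth
  regenerated <- do.call(rbind, lapply(seq_len(nrow(sv$precursors)),
    function(i) {
      enumerate_mature_forms(sv$precursors[i, c(
        "id", "sequence", "signal_end", "propeptide_end", "source"
      )])
    }))
  expect_identical(regenerated, sv$truth)
})

test_that("motif mix is honored: a GK-only venom is fully amidated", {
  spec <- synthetic_venom_spec(
    n_precursors = 5,
    motif_probs = c(GK = 1, G = 0, EK = 0, cys = 0, plain = 0),
    seed = 17
  )
  sv <- generate_precursors(spec)
  expect_true(all(sv$precursors$motif == "GK"))
  # every precursor contributes exactly one amidated ground-truth form
  amides <- tapply(sv$truth$c_term == "amide", sv$truth$parent_id, sum)
  expect_true(all(amides == 1))
})

test_that("zero spacer repeats means nothing to remove", {
  spec <- synthetic_venom_spec(n_precursors = 3, spacer_repeats = 0L,
                               seed = 29)
  sv <- generate_precursors(spec)
  expect_true(all(sv$precursors$signal_end == sv$precursors$propeptide_end))
  for (i in 1:3) {
    pro <- strip_signal(sv$precursors[i, ])
    expect_identical(process_propeptide(pro)$dipeptides, character(0))
  }
})

test_that("observed masses carry calibrated noise and identifiable decoys", {
  spec <- synthetic_venom_spec(n_precursors = 6, mass_noise_ppm = 3,
                               n_decoys = 8, seed = 41)
  sv <- generate_precursors(spec)
  obs <- generate_observed(sv$truth, spec)
  expect_identical(nrow(obs$observed),
                   nrow(sv$truth) + spec$n_decoys)
  true_rows <- !obs$assignments$is_decoy
  ppm_err <- (obs$observed$mass[true_rows] -
                obs$assignments$true_mass[true_rows]) /
    obs$assignments$true_mass[true_rows] * 1e6
  expect_lt(max(abs(ppm_err)), 20)  # a few sigma of 3 ppm
  # decoys are far from every true mass
  for (m in obs$observed$mass[obs$assignments$is_decoy]) {
    expect_gt(min(abs(m - sv$truth$mass)), 0.4)
  }
  # decoys-only input leaves everything unassigned
  decoy_obs <- obs$observed[obs$assignments$is_decoy, ]
  asn <- match_masses(decoy_obs, sv$truth)
  expect_true(all(asn$status == "unassigned"))
})
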