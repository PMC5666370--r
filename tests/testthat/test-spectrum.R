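test_that("deconvolution inverts charge projection exactly", {
  expect_equal(deconvolute(1031.5520, 2), 2061.0895, tolerance = 1e-4)
  expect_equal(deconvolute(688.0371, 3), 2061.0895, tolerance = 1e-4)
  expect_error(deconvolute(500, 0), "positive")
  expect_error(deconvolute(0.5, 1), "proton")

  set.seed(7)
  masses <- runif(200, 500, 8000)
  for (z in 1:5) {
    expect_equal(deconvolute(charge_project(masses, z), z), masses,
                 tolerance = 1e-9)
  }
})

test_that("mass matching assigns within tolerance, ties and leftovers correctly", {
  cand <- tibble::tibble(
    candidate_id = c("a", "b", "c"),
    sequence = c("AAAAA", "CCCCC", "DDDDD"),
    mass = c(1000.000, 1000.010, 2500.000)
  )
  obs <- observed_masses(c(1000.005, 2500.001, 3000.0),
                         rt = c(1, 2, 3),
                         label = c("o1", "o2", "o3"))
  asn <- match_masses(obs, cand, tol_ppm = 10, tol_da = 0.02)
  # o1 is within tolerance of both near-isobaric candidates: ambiguous,
  # both listed, sorted by |error|
  o1 <- asn[asn$label == "o1", ]
  expect_identical(unique(o1$status), "ambiguous")
  expect_identical(o1$candidate_id, c("a", "b"))
  expect_true(all(diff(abs(o1$error_da)) >= 0))
  expect_identical(asn$status[asn$label == "o2"], "unique")
  expect_identical(asn$status[asn$label == "o3"], "unassigned")
  # no observation is lost
  expect_setequal(unique(asn$label), obs$label)

  # ppm errors carried for every assignment
  o2 <- asn[asn$label == "o2", ]
  expect_equal(o2$error_ppm, o2$error_da / o2$theoretical * 1e6)

  expect_warning(match_masses(obs, cand[0, ]), "empty candidate")
})

test_that("shrinking the tolerance never assigns more masses", {
  set.seed(31)
  cand <- tibble::tibble(
    candidate_id = sprintf("c%02d", 1:30),
    sequence = random_sequences(30, seed = 31),
    mass = runif(30, 800, 4000)
  )
  obs <- observed_masses(cand$mass * (1 + rnorm(30, 0, 8e-6)),
                         label = sprintf("o%02d", 1:30))
  tols <- c(1, 2, 5, 10, 20, 50)
  assigned <- vapply(tols, function(tp) {
    asn <- match_masses(obs, cand, tol_ppm = tp, tol_da = 1e-6)
    sum(asn$status != "unassigned" & !duplicated(asn$label))
  }, numeric(1))
  expect_true(all(diff(assigned) >= 0))
})

test_that("b/y fragment ions match hand-computed values and counts", {
  ions <- fragment_ions("GWGSLFK")
  expect_identical(nrow(ions), 2L * (7L - 1L))
  expect_equal(ions$mz[ions$ion == "b2"], 244.108, tolerance = 1e-3)
  expect_equal(ions$mz[ions$ion == "y1"], 147.113, tolerance = 1e-3)
  # y(n-1) + b1 residue content spans the molecule: y ions carry the
  # C-terminal state, so the amide y series is 0.98402 lighter
  free <- fragment_ions("GWGSLFK", "free_acid")
  amide <- fragment_ions("GWGSLFK", "amide")
  expect_equal(
    amide$mz[amide$series == "y"] - free$mz[free$series == "y"],
    rep(-0.98402, 6), tolerance = 1e-5
  )
  expect_equal(amide$mz[amide$series == "b"], free$mz[free$series == "b"])
  # doubly charged series present on request
  z2 <- fragment_ions("GWGSLFK", max_charge = 2)
  expect_identical(nrow(z2), 4L * (7L - 1L))
  expect_error(fragment_ions("G"), "2 residues")
})

test_that("MS/MS scoring is complete on its own ions and penalizes decoys", {
  ions <- fragment_ions("GWGSLFKVMDK")
  pl <- peak_list(ions$mz, precursor_mz = charge_project(
    peptide_mass("GWGSLFKVMDK"), 2L), precursor_z = 2L)
  self <- score_msms(pl, list(sequence = "GWGSLFKVMDK",
                              c_term = "free_acid"))
  expect_equal(self$fraction, 1.0)

  # equal-mass decoys (shuffles) match strictly fewer ions across seeds
  set.seed(5)
  for (i in 1:10) {
    shuffled <- paste(sample(strsplit("GWGSLFKVMDK", "")[[1]]),
                      collapse = "")
    if (shuffled == "GWGSLFKVMDK") next
    dec <- score_msms(pl, list(sequence = shuffled, c_term = "free_acid"))
    expect_lt(dec$fraction, self$fraction)
  }

  # dropout reduces coverage proportionally
  set.seed(9)
  keep <- runif(nrow(ions)) >= 0.5
  half <- score_msms(peak_list(ions$mz[keep]),
                     list(sequence = "GWGSLFKVMDK", c_term = "free_acid"))
  expect_equal(half$fraction, mean(keep), tolerance = 1e-9)

  expect_warning(
    zero <- score_msms(peak_list(numeric(0)),
                       list(sequence = "GWGSLFKVMDK",
                            c_term = "free_acid")),
    "empty peak list"
  )
  expect_identical(zero$matched, 0L)
  expect_true(zero$empty_peaklist)
  expect_error(
    score_msms(pl, tibble::tibble(sequence = "ACK", c_term = "free_acid",
                                  multimer = "disulfide_homodimer")),
    "monomer"
  )
})

test_that("virtual fractionation bins by retention time", {
  obs <- observed_masses(c(1000, 1001, 1002), rt = c(5.0, 5.4, 7.2))
  binned <- virtual_fractions(obs, bin_width = 0.5)
  expect_identical(binned$fraction, c(1L, 1L, 5L))
})
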