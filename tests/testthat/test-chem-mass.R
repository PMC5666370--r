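test_that("formula parsing, formatting and arithmetic are exact and invertible", {
  f <- parse_formula("C95H152N24O23S2")
  expect_s3_class(f, "elemental_formula")
  expect_identical(format_formula(f), "C95H152N24O23S2")
  # omitted count means one
  expect_identical(format_formula(parse_formula("C2H5NO2")), "C2H5N1O2")

  water <- parse_formula("H2O")
  # commutative / associative / add-then-subtract restores
  expect_true((f + water) == (water + f))
  expect_true(((f + water) + water) == (f + (water + water)))
  expect_true((f + water - water) == f)
  expect_true((f * 2L) == (f + f))

  # subtraction below zero is a chemistry error, not a silent clamp
  expect_error(parse_formula("H2O") - parse_formula("S"), "negative")
  expect_error(formula_mass(elemental_formula(c(Xx = 1))), "Xx")
})

test_that("formula masses reproduce fixed-constant values", {
  expect_equal(formula_mass(elemental_formula()), 0)
  expect_equal(round(formula_mass(parse_formula("H2O")), 4), 18.0106)
  expect_equal(round(formula_mass(parse_formula("C95H152N24O23S2")), 3),
               2061.090)
  # average mode is heavier than monoisotopic for any real molecule
  expect_gt(formula_mass(parse_formula("C95H152N24O23S2"), "average"),
            formula_mass(parse_formula("C95H152N24O23S2")))
})

test_that("peptide formulas cover terminal states, modifications and dimers", {
  expect_identical(format_formula(peptide_formula("G")), "C2H5N1O2")
  expect_identical(
    format_formula(peptide_formula("GILDWGKKVMDWIKDKM", c_term = "amide")),
    "C95H152N24O23S2"
  )
  expect_identical(
    format_formula(peptide_formula("GVKELFGKAWGLVKKHLPKACGLLGYVKQ",
                                   multimer = "disulfide_homodimer")),
    "C300H484N78O68S2"
  )
  # a dimer needs a cysteine; oxidation needs a Met at that position
  expect_error(peptide_formula("GAK", multimer = "disulfide_homodimer"),
               "cysteine")
  expect_error(
    peptide_formula("GMK", residue_mods = list(list(pos = 1, mod = "met_oxide"))),
    "requires residue M"
  )
  expect_error(peptide_formula("GXZ"), "non-standard")
})

test_that("modification deltas are the canonical mass shifts", {
  seqs <- random_sequences(200, seed = 11)
  free <- vapply(seqs, peptide_mass, numeric(1), USE.NAMES = FALSE)
  amide <- vapply(seqs, peptide_mass, numeric(1), c_term = "amide",
                  USE.NAMES = FALSE)
  expect_equal(amide - free, rep(-0.98402, length(seqs)), tolerance = 1e-5)

  with_met <- paste0(seqs, "M")
  ox <- vapply(seq_along(with_met), function(i) {
    peptide_mass(with_met[i],
                 residue_mods = list(list(pos = nchar(with_met[i]),
                                          mod = "met_oxide")))
  }, numeric(1))
  plain <- vapply(with_met, peptide_mass, numeric(1), USE.NAMES = FALSE)
  expect_equal(ox - plain, rep(15.99491, length(seqs)), tolerance = 1e-5)

  with_cys <- paste0(seqs, "C")
  dimer <- vapply(with_cys, peptide_mass, numeric(1),
                  multimer = "disulfide_homodimer", USE.NAMES = FALSE)
  mono <- vapply(with_cys, peptide_mass, numeric(1), USE.NAMES = FALSE)
  expect_equal(dimer - 2 * mono, rep(-2.01565, length(seqs)),
               tolerance = 1e-6)
})

test_that("two independent mass routes agree and L/I are interchangeable", {
  seqs <- random_sequences(100, seed = 23)
  for (s in seqs) {
    expect_equal(peptide_mass(s), residue_sum_mass(s), tolerance = 1e-6)
  }
  swapped <- chartr("LI", "IL", seqs)
  expect_equal(vapply(swapped, peptide_mass, numeric(1), USE.NAMES = FALSE),
               vapply(seqs, peptide_mass, numeric(1), USE.NAMES = FALSE))
  expect_identical(format_formula(peptide_formula("GWGSLFK")),
                   format_formula(peptide_formula("GWGSIFK")))
})

test_that("amino acid table is consistent with its own formulas", {
  tab <- amino_acid_table()
  expect_identical(nrow(tab), 20L)
  recomputed <- vapply(tab$formula, function(f) formula_mass(parse_formula(f)),
                       numeric(1), USE.NAMES = FALSE)
  expect_equal(tab$mass, recomputed, tolerance = 1e-9)
})
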