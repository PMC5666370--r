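test_that("signal stripping honors the annotated cleavage site", {
  p <- precursor_record("p1", "MKPSLLLAEAEPGWGSIFKT", signal_end = 8)
  expect_identical(strip_signal(p), "EAEPGWGSIFKT")
  expect_error(precursor_record("p0", "MKPS", signal_end = 0), "signal_end")
  expect_error(precursor_record("p0", "MKPS", signal_end = 4), "signal_end")
})

test_that("dipeptidyl-peptidase processing removes X-P/X-A pairs and restores on concat", {
  res <- process_propeptide("EAEPDAGWGSIFK")
  expect_identical(res$dipeptides, c("EA", "EP", "DA"))
  expect_identical(res$mature, "GWGSIFK")
  expect_identical(res$mature_start, 6L)
  # removals concatenate with the remainder to restore the input
  expect_identical(paste0(paste(res$dipeptides, collapse = ""), res$mature),
                   "EAEPDAGWGSIFK")
  # every removed pair has P or A second
  expect_true(all(substring(res$dipeptides, 2, 2) %in% c("P", "A")))

  none <- process_propeptide("GWGSIFK")
  expect_identical(none$dipeptides, character(0))
  expect_identical(none$mature, "GWGSIFK")
})

test_that("mature-form enumeration implements the C-terminal motif rules", {
  mk <- function(mature) {
    precursor_record("x", paste0("MKPSLLLA", mature), signal_end = 8,
                     propeptide_end = 8)
  }

  gk <- enumerate_mature_forms(mk("GILDWGKKVMDWIKDKMGK"))
  expect_setequal(
    paste(gk$sequence, gk$c_term),
    c("GILDWGKKVMDWIKDKMGK free_acid",
      "GILDWGKKVMDWIKDKMG free_acid",
      "GILDWGKKVMDWIKDKM amide")
  )
  expect_equal(sort(round(gk$mass, 3)),
               c(2061.090, 2119.096, 2247.191))
  amide_row <- gk[gk$c_term == "amide", ]
  expect_identical(amide_row$trimmed, "GK")

  ek <- enumerate_mature_forms(mk("KIKWGKIFKKGGKLIGKTALEAAANAAASEAISAMASQNEK"))
  expect_equal(sort(round(ek$mass, 3)), c(4101.241, 4229.336))

  # lysine not preceded by glutamate is kept unless the rule is relaxed
  plain_k <- enumerate_mature_forms(mk("GIKWGDKAGK"), amidation = FALSE)
  expect_identical(nrow(plain_k), 1L)
  relaxed <- enumerate_mature_forms(mk("GIKWGDKADK"), des_k_any = TRUE)
  expect_setequal(relaxed$trimmed, c("none", "K"))

  cys <- enumerate_mature_forms(mk("GVKELFGKAWGLVKKHLPKACGLLGYVKQ"))
  expect_identical(sum(cys$multimer == "disulfide_homodimer"), 1L)
  expect_equal(round(cys$mass[cys$multimer == "disulfide_homodimer"], 3),
               6331.625)
  expect_warning(enumerate_mature_forms(mk("GCKWGDKACGIK")), "cysteine")
})

test_that("every candidate mass equals an independent recomputation", {
  p <- plp_precursors()
  forms <- do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
    enumerate_mature_forms(p[i, ])
  }))
  recomputed <- vapply(seq_len(nrow(forms)), function(i) {
    peptide_mass(forms$sequence[i], c_term = forms$c_term[i],
                 multimer = forms$multimer[i])
  }, numeric(1))
  expect_equal(forms$mass, recomputed, tolerance = 1e-9)
  expect_identical(forms$formula, vapply(seq_len(nrow(forms)), function(i) {
    format_formula(peptide_formula(forms$sequence[i], forms$c_term[i],
                                   multimer = forms$multimer[i]))
  }, character(1)))
})

test_that("truncation ladder has the predicted size and inheritance", {
  parent <- tibble::tibble(
    parent_id = "p", sequence = "GILDWGKKVMDW", c_term = "amide",
    trimmed = "GK", multimer = "monomer", provenance = "full",
    formula = "", mass = peptide_mass("GILDWGKKVMDW", "amide")
  )
  lad <- truncation_ladder(parent, min_length = 5)
  n <- nchar(parent$sequence)
  m <- 5L
  expect_identical(nrow(lad), (n - m + 1L) * 2L - 1L)
  # prefixes are free acids; suffixes inherit the amide
  expect_true(all(lad$c_term[lad$provenance == "prefix-truncation"] ==
                    "free_acid"))
  expect_true(all(lad$c_term[lad$provenance == "suffix-truncation"] ==
                    "amide"))
  # boundary: min_length equal to the length gives only the full form
  short <- truncation_ladder(
    tibble::tibble(parent_id = "p", sequence = "GWGSLFK",
                   c_term = "free_acid", trimmed = "none",
                   multimer = "monomer", provenance = "full", formula = "",
                   mass = peptide_mass("GWGSLFK")),
    min_length = 7
  )
  expect_identical(nrow(short), 1L)
  expect_error(truncation_ladder(within(parent,
                                        multimer <- "disulfide_homodimer")),
               "monomeric")
})
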