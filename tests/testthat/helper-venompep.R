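# shared test helpers: random peptide sequences over the 20 standard letters
aa_letters <- function() amino_acid_table()$residue

random_sequences <- function(n, min_len = 5, max_len = 40, seed = 42) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    paste(sample(aa_letters(), len, replace = TRUE), collapse = "")
  }, character(1))
}

# residue-sum mass route, independent of the formula-accumulation path:
# table lookup of residue masses plus the water constant
residue_sum_mass <- function(sequence) {
  tab <- amino_acid_table()
  masses <- tab$mass[match(strsplit(sequence, "")[[1]], tab$residue)]
  sum(masses) + 2 * 1.0078250319 + 15.9949146221
}
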