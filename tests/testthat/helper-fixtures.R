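# Shared fixtures, built in code. Kept small: module tests use hundreds to
# a few thousand reads; the heavier recovery runs live in the acceptance
# tests.

fixture_homolog_pair <- function() {
  make_artificial_template(1100, 9, seed = 1)
}

fixture_structured <- function() {
  # geometry of the larger inverted repeat: stem 10, loop 129, near the
  # 5' end of a 1353-nt amplicon
  make_structured_template(1353, 45, 10, 129, seed = 3)
}

fixture_small_element <- function() {
  # small element: stem 8, loop 5, near the 3' end
  make_structured_template(1353, 1285, 8, 5, seed = 4)
}

# a bare single-template set for constructed-read tests
fixture_amplicon <- function(seq, name = "amp", primer = NULL) {
  template_set(stats::setNames(seq, name), "amplicon",
               primer_regions = primer)
}

# hand-build a read row aligned to a reference
make_read <- function(sequence, ref = "amp", read_id = "r1", strand = "+",
                      pos = 1L, cigar = paste0(nchar(sequence), "M"),
                      n_passes = 20L, mapq = 254L,
                      qual = strrep("~", nchar(sequence))) {
  data.frame(read_id = read_id, ref = ref, strand = strand, pos = pos,
             cigar = cigar, sequence = sequence, n_passes = n_passes,
             mapq = mapq, qual = qual, aligned = TRUE,
             stringsAsFactors = FALSE)
}

# brute-force switch counter: scan all pairs of consecutive valid calls
brute_force_switches <- function(calls) {
  valid <- which(calls != "invalid")
  n <- 0L
  if (length(valid) >= 2L)
    for (k in 2:length(valid))
      if (calls[valid[k]] != calls[valid[k - 1L]]) n <- n + 1L
  n
}
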