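# Generator specifications that emulate the architecture of the three
# published canine cyclovirus genomes (dimensions used as study conditions;
# the sequences themselves are synthetic).

cn9e_style_spec <- function() {
  genome_spec(genome_len = 1826L, motif = "TAGTATTAC", rep_table = 5L,
              rep_start_codon = "ATA", intron_len = 56L, rep_len_aa = 292L,
              cp_len_aa = 258L, ir3_len = 0L)
}

cn16e_style_spec <- function() {
  genome_spec(genome_len = 1909L, motif = "TACTATTAC", rep_table = 1L,
              rep_start_codon = "ATG", intron_len = 0L, rep_len_aa = 280L,
              cp_len_aa = 295L, ir3_len = 4L)
}

# does the unrooted tree contain a bipartition isolating `pair`?
has_sibling_pair <- function(tr, pair) {
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  for (p in parts) {
    tips <- labs[p]
    if (setequal(tips, pair) || setequal(setdiff(labs, tips), pair)) {
      return(TRUE)
    }
  }
  FALSE
}
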