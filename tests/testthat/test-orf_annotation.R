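test_that("linear ORF enumeration matches the brute-force 6-frame oracle", {
  set.seed(91)
  for (i in 1:40) {
    L <- sample(300:900, 1)
    tb <- sample(c(1L, 5L), 1)
    s <- random_dna(L)
    g <- circular_genome("lin", s, topology = "linear")
    got <- enumerate_orfs(g, tb, min_aa = 20L)
    want <- oracle_orfs_linear(s, tb, min_aa = 20L)
    key <- function(d) sort(paste(d$strand, d$start_nt, d$end_nt, d$aa_len,
                                  d$protein))
    expect_equal(key(got), key(want))
  }
})

test_that("ORFs wrapping the circular origin are recovered in one piece", {
  set.seed(101)
  prot <- paste0("M", paste(sample(c("A", "E", "Q", "P", "H"), 119,
                                   replace = TRUE), collapse = ""))
  cds <- paste0("ATG", encode_protein(substr(prot, 2, 120)), "TAA")
  # anchor stop upstream so the ORF is stop-to-stop delimited
  base <- paste0("TAA", cds, random_dna(200))
  g0 <- circular_genome("w", base)
  # rotate so the CDS spans position one
  g <- rotate(g0, 100L)
  orfs <- enumerate_orfs(g, 1L, min_aa = 100L)
  hit <- orfs[orfs$strand == "sense" & orfs$aa_len == 120L, ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$wraps)
  expect_equal(hit$protein, prot)
  # same ORF, same coordinates modulo rotation
  L <- nchar(base)
  expect_equal(hit$start_nt, ((4L - 100L) %% L) + 1L)
})

test_that("start preference takes the 5'-most ATG, else an alternative", {
  # no ATG in frame: TTG initiates
  cds_noatg <- paste0("TTG", encode_protein(strrep("Q", 30)), "TAA")
  g <- circular_genome("s1", paste0("TAA", cds_noatg, random_dna(60)),
                       topology = "linear")
  orfs <- enumerate_orfs(g, 1L, min_aa = 25L)
  expect_true(any(orfs$init_codon == "TTG" & orfs$aa_len == 31L))
  # an ATG downstream of a TTG wins despite being 3' of it
  cds_both <- paste0("TTG", "CAGCAG", "ATG",
                     encode_protein(strrep("Q", 30)), "TAA")
  g2 <- circular_genome("s2", paste0("TAA", cds_both, random_dna(60)),
                        topology = "linear")
  orfs2 <- enumerate_orfs(g2, 1L, min_aa = 25L)
  hit <- orfs2[orfs2$strand == "sense" & orfs2$start_nt == 13L, ]
  expect_equal(hit$init_codon, "ATG")
})

test_that("planted intron boundaries and spliced Rep are recovered", {
  set.seed(111)
  for (s in 1:6) {
    sp <- genome_spec(rep_table = 5L, rep_start_codon = "ATA",
                      intron_len = 56L, rep_len_aa = 220L, cp_len_aa = 150L,
                      ir3_len = 0L)
    gg <- generate_genome(sp, seed = 1000 + s, id = "spl",
                          random_orientation = FALSE)
    spl <- find_spliced_rep(gg$genome, 5L, min_aa = 100L)
    expect_false(is.null(spl))
    expect_equal(spl$intron, gg$truth$intron)
    expect_equal(spl$aa_len, 220L)
    expect_equal(spl$init_codon, "ATA")
    expect_equal(spl$motif_score, 6L)
    expect_equal(spl$segments, gg$truth$rep_segments)
    # excised intron is canonical GT..AG on the coding orientation
    intron_seq <- region_seq(gg$genome, spl$intron[1], spl$intron[2],
                             "antisense")
    expect_equal(substr(intron_seq, 1, 2), "GT")
    expect_equal(substr(intron_seq, 55, 56), "AG")
  }
})

test_that("a motif-complete unspliced Rep never gains a spurious intron", {
  set.seed(121)
  for (s in 1:5) {
    gg <- generate_genome(genome_spec(), seed = 2000 + s,
                          random_orientation = FALSE)
    expect_null(find_spliced_rep(gg$genome, 1L))
  }
})

test_that("roles and intergenic regions are assigned from planted truth", {
  set.seed(131)
  for (s in 1:6) {
    ir3_len <- sample(c(0L, 4L, 30L), 1)
    gg <- generate_genome(genome_spec(ir3_len = ir3_len), seed = 3000 + s,
                          random_orientation = FALSE)
    orfs <- enumerate_orfs(gg$genome, 1L, min_aa = 100L)
    roles <- assign_roles(orfs, NULL, gg$genome)
    expect_true(roles$complete)
    expect_equal(c(roles$rep$start_nt, roles$rep$end_nt), gg$truth$rep)
    expect_equal(c(roles$cp$start_nt, roles$cp$end_nt), gg$truth$cp)
    expect_equal(roles$ir5, gg$truth$ir5)
    if (ir3_len == 0L) expect_null(roles$ir3) else
      expect_equal(roles$ir3, gg$truth$ir3)
  }
})

test_that("every emitted ORF satisfies the type invariants", {
  set.seed(141)
  for (i in 1:10) {
    g <- circular_genome("inv", random_dna(sample(500:1500, 1)))
    orfs <- enumerate_orfs(g, sample(c(1L, 4L, 5L), 1), min_aa = 30L)
    if (nrow(orfs) == 0L) next
    for (r in seq_len(nrow(orfs))) {
      o <- orfs[r, ]
      expect_equal(substr(o$protein, 1, 1), "M")
      expect_false(grepl("*", o$protein, fixed = TRUE))
      len <- region_length(o$start_nt, o$end_nt, nchar(g$seq),
                           if (o$strand == "sense") "sense" else "antisense")
      expect_equal(len %% 3L, 0L)
      expect_equal(o$aa_len, len / 3L - 1L)
    }
  }
})
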