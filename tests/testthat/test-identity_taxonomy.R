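test_that("identity handles exact, mismatch and gap cases analytically", {
  set.seed(171)
  s <- random_dna(1909)
  expect_equal(pairwise_identity(global_align(s, s)), 100)
  # 10 nt, one substitution, no gaps
  a <- "ACGTACGTAC"; b <- "ACGTACGTAA"
  expect_equal(pairwise_identity(global_align(a, b)), 90)
  # one internal deletion: 3 identities over 4 columns
  aln <- global_align("ACGT", "ACT")
  expect_equal(sum(strsplit(aln$b, "")[[1]] == "-"), 1L)
  expect_equal(pairwise_identity(aln), 75)
  # N counts as mismatch even against N
  expect_equal(pairwise_identity(global_align("ANNA", "ANNA")), 50)
  # the optimal score under default scoring is never below the score of the
  # alignment produced under a harsher gap regime, rescored under defaults
  rescore <- function(aln) {
    pa <- strsplit(aln$a, "")[[1]]; pb <- strsplit(aln$b, "")[[1]]
    sc <- 0; in_gap <- FALSE
    for (k in seq_along(pa)) {
      if (pa[k] == "-" || pb[k] == "-") {
        sc <- sc - (if (in_gap) 0.5 else 10.5); in_gap <- TRUE
      } else {
        sc <- sc + (if (pa[k] == pb[k]) 5 else -4); in_gap <- FALSE
      }
    }
    sc
  }
  for (i in 1:10) {
    x <- random_dna(40); y <- random_dna(35)
    opt <- global_align(x, y)
    alt <- global_align(x, y, gap_open = 25, gap_extend = 2)
    expect_gte(opt$score, rescore(alt) - 1e-6)
  }
})

test_that("identity is symmetric and invariant under joint revcomp", {
  set.seed(181)
  for (i in 1:8) {
    a <- random_dna(300)
    b <- mutate_genome(circular_genome("b", a), 0.1)$seq
    i1 <- pairwise_identity(global_align(a, b))
    i2 <- pairwise_identity(global_align(b, a))
    i3 <- pairwise_identity(global_align(revcomp(a), revcomp(b)))
    expect_equal(i1, i2, tolerance = 1e-9)
    expect_equal(i1, i3, tolerance = 1e-9)
  }
})

test_that("mixed alphabets are rejected", {
  expect_error(global_align("ACGT", "MKWQE"), "mixed alphabets")
})

test_that("identity matrices are symmetric with unit diagonal", {
  set.seed(191)
  seqs <- c(a = random_dna(400))
  seqs["b"] <- mutate_genome(circular_genome("x", seqs["a"]), 0.02)$seq
  seqs["c"] <- mutate_genome(circular_genome("x", seqs["a"]), 0.3)$seq
  m <- identity_matrix(seqs)
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_true(all(m >= 0 & m <= 100))
  expect_error(identity_matrix(c(a = "ACGT", a = "ACGT")), "duplicate")
})

test_that("species demarcation reproduces known clusters and the graph oracle", {
  m <- matrix(c(100, 59.704, 59.642,
                59.704, 100, 99.790,
                59.642, 99.790, 100), 3, 3,
              dimnames = list(c("CN9E", "CN16E", "CN34"),
                              c("CN9E", "CN16E", "CN34")))
  sp <- demarcate_species(m, 80)
  expect_equal(sp$n_clusters, 2L)
  expect_equal(unname(sp$clusters["CN9E"]), 1L)
  expect_equal(unname(sp$clusters["CN16E"]), unname(sp$clusters["CN34"]))
  expect_equal(demarcate_species(m, 0)$n_clusters, 1L)
  # threshold 100 separates all non-identical sequences
  expect_equal(demarcate_species(m, 100)$n_clusters, 3L)
  set.seed(201)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    mm <- matrix(runif(k * k, 0, 100), k, k)
    mm <- (mm + t(mm)) / 2
    diag(mm) <- 100
    dimnames(mm) <- list(letters[1:k], letters[1:k])
    thr <- runif(1, 20, 95)
    got <- demarcate_species(mm, thr)$clusters
    want <- oracle_components(mm, thr)
    # same partition up to cluster relabeling
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("raising the threshold never merges clusters", {
  set.seed(211)
  for (i in 1:10) {
    k <- sample(4:8, 1)
    mm <- matrix(runif(k * k, 0, 100), k, k)
    mm <- (mm + t(mm)) / 2; diag(mm) <- 100
    dimnames(mm) <- list(letters[1:k], letters[1:k])
    lo <- demarcate_species(mm, 40)$clusters
    hi <- demarcate_species(mm, 75)$clusters
    # clusters at the higher threshold refine those at the lower one
    same_hi <- outer(hi, hi, "==")
    same_lo <- outer(lo, lo, "==")
    expect_true(all(same_lo[same_hi]))
  }
})

test_that("genus classification follows genome organization", {
  set.seed(221)
  gg <- generate_genome(genome_spec(), seed = 6000,
                        random_orientation = FALSE)
  ref <- mutate_genome(gg$genome, 0.2)$seq
  ann <- annotate_genome(gg$genome, refs = c(ref1 = ref))
  expect_equal(ann$genus$call, "cyclovirus-like")
  expect_true(ann$genus$evidence[["ori_on_cp_strand"]])
  expect_true(ann$genus$evidence[["motif_complete_rep"]])
  expect_true(ann$genus$evidence[["arg_rich_cp"]])

  # circovirus-style construct: the motif-bearing strand carries Rep itself
  rep_aa <- paste0("M", strrep("Q", 12), "FTLNN", strrep("E", 20), "AHVQG",
                   strrep("A", 25), "YCSK", strrep("Q", 55), "GPPGTGKS",
                   strrep("E", 20), "LLFDD", strrep("A", 15), "LTSN",
                   strrep("Q", 8))
  rep_cds <- paste0(encode_protein(rep_aa), "TAA")
  circo <- circular_genome("circo", paste0(
    "TAGTATTAC", "G", "GCGGAGGCC", "TAA", rep_cds,
    random_dna(120), revcomp("GCGGAGGCC")))
  # place the stem arm before the motif by rotating the arm into the tail
  ann2 <- annotate_genome(circo)
  expect_equal(ann2$genus$call, "circovirus-like")

  # no nonanucleotide motif at all
  ann3 <- annotate_genome(circular_genome("none", strrep("C", 500)))
  expect_equal(ann3$genus$call, "unclassified")
})

test_that("identity matrix TSV round-trips", {
  m <- matrix(c(100, 60, 60, 100), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  tf <- tempfile(fileext = ".tsv")
  write_identity_tsv(m, tf)
  back <- read_identity_tsv(tf)
  expect_equal(unclass(back), m, ignore_attr = TRUE)
})
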