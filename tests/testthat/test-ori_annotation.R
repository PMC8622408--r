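test_that("canonical and one-mismatch nonanucleotide motifs are found", {
  set.seed(21)
  flank1 <- random_dna(200); flank2 <- random_dna(200)
  g <- circular_genome("m", paste0(flank1, "TAGTATTAC", flank2))
  hits <- find_nonanucleotide(g, "NAGTATTAC", 0L)
  planted <- hits[hits$start_nt == 201 & hits$strand == "sense", ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$mismatches, 0L)
  expect_equal(planted$motif_seq, "TAGTATTAC")
  # the single-nt variant needs one mismatch against the consensus
  g2 <- circular_genome("m2", paste0(flank1, "TACTATTAC", flank2))
  expect_equal(nrow(find_nonanucleotide(g2, "NAGTATTAC", 0L)[
    find_nonanucleotide(g2, "NAGTATTAC", 0L)$start_nt == 201, ]), 0L)
  h2 <- find_nonanucleotide(g2, "NAGTATTAC", 1L)
  h2 <- h2[h2$start_nt == 201 & h2$strand == "sense", ]
  expect_equal(h2$mismatches, 1L)
})

test_that("motif scan equals the brute-force window oracle", {
  set.seed(31)
  for (i in 1:20) {
    g <- circular_genome("r", random_dna(sample(100:400, 1)))
    got <- find_nonanucleotide(g, "NAGTATTAC", 1L)
    want <- oracle_nona(g$seq, "NAGTATTAC", 1L)
    key <- function(d) sort(paste(d$start_nt, d$strand, d$mismatches))
    expect_equal(key(got), key(want))
  }
})

test_that("motif scan is strand-symmetric", {
  set.seed(41)
  for (i in 1:10) {
    L <- sample(150:400, 1)
    g <- circular_genome("s", paste0(random_dna(L), "TAGTATTAC"))
    rc <- circular_genome("s", revcomp(g$seq))
    a <- find_nonanucleotide(g, "NAGTATTAC", 1L)
    b <- find_nonanucleotide(rc, "NAGTATTAC", 1L)
    swap <- c(sense = "antisense", antisense = "sense")
    Lg <- nchar(g$seq)
    key <- function(d, flip) {
      strand <- d$strand; start <- d$start_nt
      if (flip) {            # position p maps to L - p + 1 under revcomp
        strand <- unname(swap[strand])
        start <- Lg - start + 1L
      }
      sort(paste(start, strand, d$mismatches))
    }
    expect_equal(key(a, FALSE), key(b, TRUE))
  }
})

test_that("stem-loop search finds a planted hairpin and rejects none", {
  set.seed(51)
  arm <- "GCGGAGGCC"
  loop <- "TAGTATTACC"      # 10-nt loop, motif at its start
  g <- circular_genome("h", paste0(random_dna(60), arm, loop,
                                   revcomp(arm), random_dna(60)))
  hit <- data.frame(start_nt = 70L)
  sl <- predict_stem_loop(g, hit, min_arm = 5L, max_loop = 13L,
                          max_arm_mismatch = 0L, max_arm = 9L)
  expect_false(is.null(sl))
  expect_gte(sl$arm_len, 9L)
  expect_true(sl$loop[1] <= 70 && sl$loop[2] >= 70)
  # motif with alternating flanks that cannot pair
  g2 <- circular_genome("n", paste0(strrep("A", 40), "TAGTATTAC",
                                    strrep("A", 40)))
  expect_null(predict_stem_loop(g2, data.frame(start_nt = 41L),
                                min_arm = 5L, max_arm_mismatch = 0L))
})

test_that("stem-loop maximizes arm length over exhaustive enumeration", {
  set.seed(61)
  for (rep in 1:10) {
    alen <- sample(5:12, 1)
    arm <- random_dna(alen)
    u <- sample(0:2, 1); v <- sample(0:2, 1)
    if (9 + u + v > 13) v <- 0
    g <- circular_genome("e", paste0(
      random_dna(50), arm, random_dna(u), "TAGTATTAC", random_dna(v),
      revcomp(arm), random_dna(50)))
    p <- 51 + alen + u
    sl <- predict_stem_loop(g, data.frame(start_nt = p), min_arm = 5L,
                            max_loop = 13L, max_arm_mismatch = 0L,
                            max_arm = 15L)
    # independent exhaustive check of the maximal mismatch-free arm length
    chars <- strsplit(g$seq, "")[[1]]
    best <- 0L
    for (uu in 0:4) for (vv in 0:(4 - uu)) {
      ls <- p - uu; le <- p + 8 + vv
      a <- 0L
      while (a < 15) {
        i5 <- ls - a - 1L; i3 <- le + a + 1L
        if (i5 < 1 || i3 > length(chars)) break
        if (chartr("ACGT", "TGCA", chars[i5]) != chars[i3]) break
        a <- a + 1L
      }
      best <- max(best, a)
    }
    if (best >= 5L) {
      expect_equal(sl$arm_len, best)
    } else {
      expect_null(sl)
    }
  }
})

test_that("orient_and_rotate puts the motif at positions 1-9 from any phase", {
  set.seed(71)
  for (i in 1:20) {
    L <- sample(300:900, 1)
    base <- paste0("TAGTATTAC", random_dna(L - 9))
    g0 <- circular_genome("o", base)
    if (nrow(find_nonanucleotide(g0, "NAGTATTAC", 1L)) != 1L) next
    k <- sample(seq_len(L), 1)
    g <- rotate(g0, k)
    if (runif(1) < 0.5) g <- circular_genome("o", revcomp(g$seq))
    out <- orient_and_rotate(g)
    expect_equal(substr(out$genome$seq, 1, 9), "TAGTATTAC")
    expect_equal(out$genome$seq, base)
    expect_equal(out$ori$nona$start_nt, 1L)
  }
})

test_that("absent motif raises an actionable error", {
  g <- circular_genome("none", strrep("C", 400))
  expect_error(orient_and_rotate(g), "max_mismatch")
})
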