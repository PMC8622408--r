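test_that("three-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.4,
                0.5, 0.4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  # x_a = (d_ab + d_ac - d_bc)/2 etc.
  bl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), (0.3 + 0.5 - 0.4) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["b"]), (0.3 + 0.4 - 0.5) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["c"]), (0.5 + 0.4 - 0.3) / 2, tolerance = 1e-9)
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers topology and path lengths from additive matrices", {
  set.seed(231)
  for (i in 1:15) {
    n <- sample(4:12, 1)
    tr0 <- ape::rtree(n, rooted = FALSE)
    tr0$edge.length <- runif(length(tr0$edge.length), 0.05, 1)
    d <- ape::cophenetic.phylo(tr0)
    tr <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr0), tr), 0, ignore_attr = TRUE)
    d2 <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_equal(d2, d, tolerance = 1e-6)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("negative NJ branches are clamped without changing path sums", {
  # a non-additive matrix known to produce a negative NJ branch
  d <- matrix(c(0, 2, 2.1, 2.2,
                2, 0, 0.1, 0.2,
                2.1, 0.1, 0, 0.1,
                2.2, 0.2, 0.1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports deep splits and is seed-deterministic", {
  set.seed(241)
  base <- random_dna(800)
  g <- circular_genome("b", base)
  cladeA <- mutate_genome(g, 0.4, seed = 1)
  cladeB <- mutate_genome(g, 0.4, seed = 2)
  seqs <- c(A1 = mutate_genome(cladeA, 0.01, seed = 3)$seq,
            A2 = mutate_genome(cladeA, 0.01, seed = 4)$seq,
            B1 = mutate_genome(cladeB, 0.01, seed = 5)$seq,
            B2 = mutate_genome(cladeB, 0.01, seed = 6)$seq)
  tr <- bootstrap_support(seqs, replicates = 50L, seed = 9L)
  expect_true(all(as.numeric(tr$node.label[-1]) >= 95, na.rm = TRUE))
  tr2 <- bootstrap_support(seqs, replicates = 50L, seed = 9L)
  expect_identical(tr$node.label, tr2$node.label)
  # label order does not change the supports
  tr3 <- bootstrap_support(seqs[c(3, 1, 4, 2)], replicates = 50L, seed = 9L)
  expect_identical(tr$node.label, tr3$node.label)
  # no supports without replicates
  tr0 <- bootstrap_support(seqs, replicates = 0L)
  expect_null(tr0$node.label)
  # serializes to Newick
  tf <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, tf)
  expect_match(readLines(tf), "^\\(.*;$")
})

test_that("sliding-window identity flags a planted recombination breakpoint", {
  set.seed(251)
  a <- random_dna(1200)
  b <- mutate_genome(circular_genome("b", a), 0.35, seed = 7)$seq
  chimera <- circular_genome("c", paste0(substr(a, 1, 600),
                                         substr(b, 601, 1200)))
  prof <- sliding_window_identity(chimera, list(A = a, B = b),
                                  window = 200L, step = 50L)
  expect_true(all(prof$identity >= 0 & prof$identity <= 100))
  pa <- prof[prof$ref == "A", ]
  pb <- prof[prof$ref == "B", ]
  # left of the breakpoint the chimera tracks A, right of it B
  expect_true(all(pa$identity[pa$window_start <= 350] >
                  pb$identity[pb$window_start <= 350]))
  expect_true(all(pa$identity[pa$window_start >= 650] <
                  pb$identity[pb$window_start >= 650]))
  # identical query gives a flat 100 profile
  flat <- sliding_window_identity(circular_genome("q", a), list(A = a),
                                  window = 200L, step = 100L)
  expect_true(all(flat$identity == 100))
})
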