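# Independent brute-force oracles used to validate the production code.
# These deliberately use naive loops and plain string handling, not the
# package's internal machinery.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

# every-window motif scan on both strands
oracle_nona <- function(seq, consensus = "NAGTATTAC", max_mm = 1L) {
  L <- nchar(seq)
  cpat <- strsplit(consensus, "")[[1]]
  count_mm <- function(win) {
    w <- strsplit(win, "")[[1]]
    mm <- 0L
    for (j in 1:9) {
      if (w[j] == "N") mm <- mm + 1L
      else if (cpat[j] != "N" && w[j] != cpat[j]) mm <- mm + 1L
    }
    mm
  }
  res <- list()
  ext <- paste0(seq, substr(seq, 1, 8))
  for (i in 1:L) {
    mm <- count_mm(substr(ext, i, i + 8))
    if (mm <= max_mm) res[[length(res) + 1L]] <-
        data.frame(start_nt = i, strand = "sense", mismatches = mm)
  }
  rc <- oracle_revcomp(seq)
  ext <- paste0(rc, substr(rc, 1, 8))
  for (i in 1:L) {
    mm <- count_mm(substr(ext, i, i + 8))
    if (mm <= max_mm) res[[length(res) + 1L]] <-
        data.frame(start_nt = L - i + 1L, strand = "antisense",
                   mismatches = mm)
  }
  if (length(res) == 0L) return(data.frame(start_nt = integer(),
                                           strand = character(),
                                           mismatches = integer()))
  do.call(rbind, res)
}

# naive 6-frame ORF scan on a LINEAR sequence, same start policy as the
# package contract: 5'-most ATG, else 5'-most alternative start codon
oracle_orfs_linear <- function(seq, table_id = 1L,
                               start_codons = c("ATG", "ATA", "TTG", "GTG"),
                               min_aa = 20L) {
  code <- Biostrings::getGeneticCode(as.character(table_id))
  L <- nchar(seq)
  out <- list()
  for (strand in c("sense", "antisense")) {
    S <- if (strand == "sense") seq else oracle_revcomp(seq)
    for (f in 0:2) {
      pos <- f + 1L
      codon_pos <- c()
      codon_aa <- c()
      codon_str <- c()
      while (pos + 2L <= L) {
        cd <- substr(S, pos, pos + 2L)
        aa <- code[[cd]]
        if (is.null(aa) || is.na(aa)) aa <- "X"
        codon_pos <- c(codon_pos, pos)
        codon_aa <- c(codon_aa, aa)
        codon_str <- c(codon_str, cd)
        pos <- pos + 3L
      }
      stops <- which(codon_aa == "*")
      if (length(stops) == 0L) next
      bounds <- cbind(c(1L, stops[-length(stops)] + 1L), stops)
      for (r in seq_len(nrow(bounds))) {
        lo <- bounds[r, 1]; st <- bounds[r, 2]
        if (st <= lo) next
        seg <- lo:(st - 1L)
        atg <- seg[codon_str[seg] == "ATG"]
        si <- NA
        if (length(atg) > 0L) si <- atg[1] else {
          alt <- seg[codon_str[seg] %in% setdiff(start_codons, "ATG")]
          if (length(alt) > 0L) si <- alt[1]
        }
        if (is.na(si)) next
        aa_len <- st - si
        if (aa_len < min_aa) next
        p1 <- codon_pos[si]; p2 <- codon_pos[st] + 2L
        if (strand == "antisense") { p1 <- L - p1 + 1L; p2 <- L - p2 + 1L }
        prot <- c("M", codon_aa[(si + 1L):(st - 1L)])
        out[[length(out) + 1L]] <- data.frame(
          strand = strand, start_nt = p1, end_nt = p2, aa_len = aa_len,
          protein = paste(prot, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(strand = character(), start_nt = integer(),
                      end_nt = integer(), aa_len = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$strand, res$start_nt, res$end_nt), , drop = FALSE]
}

# connected components at >= threshold via boolean transitive closure
oracle_components <- function(m, threshold) {
  adj <- m >= threshold
  diag(adj) <- TRUE
  k <- nrow(adj)
  reach <- adj
  for (i in seq_len(k)) {
    reach <- (reach %*% adj) > 0
  }
  comp <- integer(k)
  cid <- 0L
  for (i in seq_len(k)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  stats::setNames(comp, rownames(m))
}

# per-codon translation comparison
oracle_code_mismatches <- function(cds, t1, t2) {
  c1 <- Biostrings::getGeneticCode(as.character(t1))
  c2 <- Biostrings::getGeneticCode(as.character(t2))
  n <- nchar(cds)
  mism <- 0L
  for (i in seq(1L, n - 5L, 3L)) {   # exclude the stop codon
    cd <- substr(cds, i, i + 2L)
    a1 <- if (i == 1L) "M" else c1[[cd]]
    a2 <- if (i == 1L) "M" else c2[[cd]]
    if (a1 != a2) mism <- mism + 1L
  }
  mism
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# simple aa -> codon encoder for hand-built constructs (table-invariant
# codons only)
encode_protein <- function(aa) {
  map <- c(A = "GCT", E = "GAG", Q = "CAG", P = "CCA", H = "CAT",
           F = "TTT", T = "ACT", L = "CTC", N = "AAT", V = "GTT",
           G = "GGT", Y = "TAT", C = "TGT", S = "AGT", K = "AAG",
           D = "GAT", W = "TGG", R = "CGT", M = "ATG", I = "ATC")
  paste(unname(map[strsplit(aa, "")[[1]]]), collapse = "")
}
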