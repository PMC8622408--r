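#' Find nonanucleotide motif hits on a circular genome
#'
#' Scans every circular window on both strands for matches to the conserved
#' nonanucleotide consensus (default \code{NAGTATTAC}) that marks the origin
#' of rolling-circle replication. \code{N} in the consensus matches any base;
#' \code{N} in the genome matches nothing and counts as a mismatch.
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param consensus 9-nt consensus pattern (IUPAC \code{N} only).
#' @param max_mismatch maximum mismatches allowed (0..3).
#' @return data frame with columns \code{motif_seq}, \code{start_nt} (1-based,
#'   virion numbering; for antisense hits the position of the motif's first
#'   base as read on the antisense strand), \code{strand} and
#'   \code{mismatches}, sorted by (mismatches, strand, position). Zero rows if
#'   no hit.
#' @export
find_nonanucleotide <- function(genome, consensus = "NAGTATTAC",
                                max_mismatch = 1L) {
  stopifnot(inherits(genome, "circular_genome"))
  consensus <- toupper(consensus)
  if (nchar(consensus) != 9L) stop("consensus must be 9 nt")
  if (max_mismatch < 0L || max_mismatch > 3L) stop("max_mismatch must be 0..3")
  L <- nchar(genome$seq)
  cpat <- strsplit(consensus, "", fixed = TRUE)[[1]]

  scan_strand <- function(s) {
    # s is the strand to scan in its own 5'->3' reading; circular windows
    chars <- strsplit(paste0(s, substr(s, 1L, 8L)), "", fixed = TRUE)[[1]]
    if (length(chars) < 9L) return(NULL)
    n <- nchar(s)
    mm <- integer(n)
    for (j in 1:9) {
      if (cpat[j] == "N") next
      mm <- mm + as.integer(chars[seq_len(n) + (j - 1L)] != cpat[j])
    }
    # N in genome counted as mismatch even vs consensus N
    for (j in 1:9) {
      if (cpat[j] == "N") {
        mm <- mm + as.integer(chars[seq_len(n) + (j - 1L)] == "N")
      }
    }
    hits <- which(mm <= max_mismatch)
    if (length(hits) == 0L) return(NULL)
    data.frame(
      motif_seq = vapply(hits, function(i)
        paste(chars[i:(i + 8L)], collapse = ""), character(1)),
      pos = hits, mismatches = mm[hits], stringsAsFactors = FALSE)
  }

  out <- list()
  fh <- scan_strand(genome$seq)
  if (!is.null(fh)) {
    fh$strand <- "sense"; fh$start_nt <- fh$pos; out <- c(out, list(fh))
  }
  rh <- scan_strand(revcomp(genome$seq))
  if (!is.null(rh)) {
    rh$strand <- "antisense"
    # first motif base at position j of revcomp = virion position L - j + 1
    rh$start_nt <- L - rh$pos + 1L
    out <- c(out, list(rh))
  }
  if (length(out) == 0L) {
    return(data.frame(motif_seq = character(), start_nt = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)[, c("motif_seq", "start_nt", "strand",
                                 "mismatches")]
  res <- res[order(res$mismatches, res$strand != "sense", res$start_nt), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict the stem-loop enclosing a nonanucleotide hit
#'
#' Deterministic complementary-arm search: among all arm lengths and loop
#' placements that keep the motif inside the loop, returns the structure
#' maximizing arm length, ties broken by smaller loop, then fewer arm
#' mismatches. This replaces thermodynamic folding: the hairpin is used only
#' to confirm the motif sits at the apex of a stem.
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param hit one row of \code{\link{find_nonanucleotide}} output (sense
#'   strand coordinates; orient the genome first for antisense hits).
#' @param min_arm minimum stem arm length (nt).
#' @param max_loop maximum loop length (nt), motif included.
#' @param max_arm_mismatch mismatches tolerated between the arms.
#' @param max_arm cap on the arm length searched.
#' @return a list of class \code{stem_loop} with fields \code{arm5},
#'   \code{arm3}, \code{loop} (each \code{c(start, end)} in virion
#'   coordinates), \code{arm_len}, \code{loop_len}, \code{arm_mismatches};
#'   or \code{NULL} if no structure meets \code{min_arm}.
#' @export
predict_stem_loop <- function(genome, hit, min_arm = 5L, max_loop = 13L,
                              max_arm_mismatch = 1L, max_arm = 20L) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- nchar(genome$seq)
  chars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
  at <- function(i) chars[((i - 1L) %% L) + 1L]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  p <- as.integer(hit$start_nt[1])

  best <- NULL
  slack <- max_loop - 9L
  if (slack < 0L) return(NULL)
  for (u in 0:slack) {          # loop bases before the motif
    for (v in 0:(slack - u)) {  # loop bases after the motif
      loop_start <- p - u
      loop_end <- p + 8L + v
      max_here <- min(max_arm, (L - (9L + u + v)) %/% 2L)
      for (alen in seq_len(max_here)) {
        a5 <- at(seq(loop_start - alen, loop_start - 1L))
        a3 <- at(seq(loop_end + 1L, loop_end + alen))
        mm <- sum(a5 != comp[rev(a3)])
        if (mm > max_arm_mismatch) next
        cand <- list(arm_len = alen, loop_len = 9L + u + v, mm = mm,
                     u = u, v = v)
        if (is.null(best) ||
            cand$arm_len > best$arm_len ||
            (cand$arm_len == best$arm_len && cand$loop_len < best$loop_len) ||
            (cand$arm_len == best$arm_len && cand$loop_len == best$loop_len &&
             cand$mm < best$mm)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best) || best$arm_len < min_arm) return(NULL)
  wrap <- function(i) ((i - 1L) %% L) + 1L
  loop_start <- p - best$u
  loop_end <- p + 8L + best$v
  structure(list(
    arm5 = c(wrap(loop_start - best$arm_len), wrap(loop_start - 1L)),
    arm3 = c(wrap(loop_end + 1L), wrap(loop_end + best$arm_len)),
    loop = c(wrap(loop_start), wrap(loop_end)),
    arm_len = best$arm_len, loop_len = best$loop_len,
    arm_mismatches = best$mm), class = "stem_loop")
}

#' Orient and rotate a genome to the position-one convention
#'
#' Picks the best nonanucleotide hit (fewest mismatches; ties broken by the
#' longest supporting stem arms, then lowest position), reverse-complements
#' the genome if the hit lies on the antisense strand, and rotates so the
#' first nt of the motif becomes position one (ICTV convention).
#'
#' @inheritParams find_nonanucleotide
#' @param min_arm,max_loop,max_arm_mismatch stem-loop search parameters used
#'   for tie-breaking and reporting (see \code{\link{predict_stem_loop}}).
#' @return list with \code{genome} (rotated, virion sense), and \code{ori}, a
#'   list of class \code{ori_annotation} holding the chosen hit (after
#'   rotation \code{start_nt = 1}), the stem-loop (or \code{NULL}), and a
#'   \code{rotated} flag.
#' @export
orient_and_rotate <- function(genome, consensus = "NAGTATTAC",
                              max_mismatch = 1L, min_arm = 5L, max_loop = 13L,
                              max_arm_mismatch = 1L) {
  hits <- find_nonanucleotide(genome, consensus, max_mismatch)
  if (nrow(hits) == 0L) {
    stop("no nonanucleotide motif found in '", genome$id,
         "'; consider relaxing max_mismatch")
  }
  cand <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  # tie-break on stem quality: evaluate each candidate in its own orientation
  arm_of <- function(i) {
    h <- cand[i, ]
    g <- if (h$strand == "antisense") {
      circular_genome(genome$id, revcomp(genome$seq), genome$topology)
    } else genome
    p <- motif_pos_in_oriented(genome, h)
    sl <- predict_stem_loop(g, data.frame(start_nt = p), min_arm = 1L,
                            max_loop = max_loop,
                            max_arm_mismatch = max_arm_mismatch)
    if (is.null(sl)) 0L else sl$arm_len
  }
  arms <- vapply(seq_len(nrow(cand)), arm_of, integer(1))
  ord <- order(-arms, cand$strand != "sense", cand$start_nt)
  pick <- cand[ord[1], ]

  if (pick$strand == "antisense") {
    genome <- circular_genome(genome$id, revcomp(genome$seq), genome$topology)
  }
  p <- motif_pos_in_oriented_raw(genome, pick)
  rotated_flag <- (p != 1L) || (pick$strand == "antisense")
  g2 <- if (genome$topology == "circular") rotate(genome, p) else genome
  sl <- predict_stem_loop(g2, data.frame(start_nt = 1L), min_arm = min_arm,
                          max_loop = max_loop,
                          max_arm_mismatch = max_arm_mismatch)
  ori <- structure(list(
    nona = data.frame(motif_seq = pick$motif_seq, start_nt = 1L,
                      strand = "sense", mismatches = pick$mismatches,
                      stringsAsFactors = FALSE),
    stem_loop = sl, rotated = rotated_flag), class = "ori_annotation")
  list(genome = g2, ori = ori)
}

# Motif start position of hit `h` in the genome after orienting to the hit's
# strand (i.e. position within revcomp(seq) for antisense hits).
motif_pos_in_oriented <- function(genome, h) {
  if (h$strand == "sense") h$start_nt else
    nchar(genome$seq) - h$start_nt + 1L
}

# Same, but `genome` has already been reverse-complemented when needed.
motif_pos_in_oriented_raw <- function(genome_oriented, h) {
  if (h$strand == "sense") h$start_nt else
    nchar(genome_oriented$seq) - h$start_nt + 1L
}
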