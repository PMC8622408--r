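# ORF enumeration on circular genomes, splice-aware Rep reconstruction,
# role assignment and intergenic regions.

#' Enumerate unspliced ORFs on a circular genome
#'
#' Scans both strands (or one) in all three frames, allowing ORFs to wrap the
#' circular origin, under a chosen translation table. ORFs are stop-anchored:
#' each reported ORF ends at a stop codon (included in its coordinates) and
#' begins at the 5'-most ATG in its frame segment, or, if there is none, at
#' the 5'-most occurrence of a configured alternative start codon.
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param table_id translation table (1, 4 or 5).
#' @param start_codons allowed initiation codons, in preference order used
#'   only when no ATG exists (default \code{ATG, ATA, TTG, GTG}).
#' @param min_aa minimum protein length (aa, stop excluded).
#' @param strands strands to scan.
#' @param exclude_start_in optional \code{c(start, end)} virion-sense span;
#'   start codons overlapping it (e.g. the ori motif) are skipped.
#' @return data frame with one row per ORF: \code{strand}, \code{start_nt},
#'   \code{end_nt} (stop codon included; descending for antisense),
#'   \code{aa_len}, \code{init_codon}, \code{wraps} (crosses position 1 on
#'   its coding strand), \code{table_id}, \code{protein}.
#' @export
enumerate_orfs <- function(genome, table_id = 1L,
                           start_codons = default_start_codons(),
                           min_aa = 100L,
                           strands = c("sense", "antisense"),
                           exclude_start_in = NULL) {
  stopifnot(inherits(genome, "circular_genome"))
  code <- genetic_code(table_id)
  start_codons <- toupper(start_codons)
  L <- nchar(genome$seq)
  circular <- genome$topology == "circular"
  rows <- list()

  for (strand in strands) {
    R <- if (strand == "sense") genome$seq else revcomp(genome$seq)
    D <- if (circular) paste0(R, R) else R
    nD <- nchar(D)
    for (f in 0:2) {
      starts <- seq.int(f + 1L, nD - 2L, 3L)
      if (length(starts) < 2L) next
      codons <- substring(D, starts, starts + 2L)
      aa <- unname(code[codons])
      aa[is.na(aa)] <- "X"
      stop_idx <- which(aa == "*")
      if (length(stop_idx) < 1L) next
      # segments between consecutive stops (and, for linear, before the first)
      seg_lo <- if (circular) stop_idx[-length(stop_idx)] + 1L else
        c(1L, stop_idx[-length(stop_idx)] + 1L)
      seg_stop <- if (circular) stop_idx[-1L] else stop_idx
      if (!circular && length(seg_lo) > length(seg_stop)) {
        seg_lo <- seg_lo[seq_along(seg_stop)]
      }
      for (k in seq_along(seg_stop)) {
        lo <- seg_lo[k]; st <- seg_stop[k]
        if (st <= lo) next
        cand <- lo:(st - 1L)
        if (!is.null(exclude_start_in)) {
          gpos <- to_virion(starts[cand], strand, L)
          drop <- gpos >= exclude_start_in[1] & gpos <= exclude_start_in[2]
          cand <- cand[!drop]
          if (length(cand) == 0L) next
        }
        sel <- cand[aa[cand] == "M" & codons[cand] == "ATG"]
        s_idx <- if (length(sel) > 0L) sel[1] else {
          alt <- cand[codons[cand] %in% setdiff(start_codons, "ATG")]
          if (length(alt) > 0L) alt[1] else NA_integer_
        }
        if (is.na(s_idx)) next
        n_codons <- st - s_idx + 1L
        if (n_codons * 3L > L) next          # ORF cannot exceed the genome
        aa_len <- n_codons - 1L
        if (aa_len < min_aa) next
        p_start <- starts[s_idx]
        p_end <- starts[st] + 2L
        prot <- c("M", aa[(s_idx + 1L):(st - 1L)])
        if (st - 1L < s_idx + 1L) prot <- "M"
        rows[[length(rows) + 1L]] <- data.frame(
          strand = strand,
          start_nt = to_virion(p_start, strand, L),
          end_nt = to_virion(p_end, strand, L),
          aa_len = aa_len,
          init_codon = codons[s_idx],
          wraps = (((p_start - 1L) %% L) + n_codons * 3L) > L,
          table_id = as.integer(table_id),
          protein = paste(prot, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(strand = character(), start_nt = integer(),
                      end_nt = integer(), aa_len = integer(),
                      init_codon = character(), wraps = logical(),
                      table_id = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("strand", "start_nt", "end_nt")]), ,
             drop = FALSE]
  out <- out[order(out$strand != "sense", -out$aa_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Map a position on a strand's own 5'->3' reading to virion-sense numbering.
to_virion <- function(pos, strand, L) {
  p <- ((pos - 1L) %% L) + 1L
  if (strand == "sense") p else L - p + 1L
}

#' Reconstruct an intron-split Rep ORF on the antisense strand
#'
#' Considers every donor (GT) / acceptor (AG) pair on the antisense strand
#' with an intron length between 4 nt and \code{max_intron}, excises the
#' intron, and looks for an in-frame, stop-free ORF crossing the splice
#' junction. Among candidates, the one maximizing (conserved Rep-motif score,
#' then protein length) is returned, and only if it strictly beats the best
#' unspliced antisense ORF on the same criterion.
#'
#' The search treats the ori-rotated genome as linear on the antisense
#' reading, reflecting cyclovirus organization where the ori lies in the
#' intergenic region so the rep gene does not span position one.
#'
#' @inheritParams enumerate_orfs
#' @param max_intron maximum intron length (nt).
#' @param patterns Rep motif patterns for scoring
#'   (\code{\link{default_rep_motif_patterns}}).
#' @return a list of class \code{spliced_orf} with fields \code{segments}
#'   (two \code{c(start_nt, end_nt)} pairs, descending virion coordinates),
#'   \code{intron} (\code{c(start_nt, end_nt)}, descending), \code{start_nt},
#'   \code{end_nt}, \code{init_codon}, \code{table_id}, \code{protein},
#'   \code{aa_len}, \code{motif_score}; or \code{NULL} if no spliced
#'   candidate beats the unspliced best.
#' @export
find_spliced_rep <- function(genome, table_id = 1L,
                             start_codons = default_start_codons(),
                             min_aa = 100L, max_intron = 200L,
                             patterns = default_rep_motif_patterns()) {
  stopifnot(inherits(genome, "circular_genome"))
  code <- genetic_code(table_id)
  start_codons <- toupper(start_codons)
  L <- nchar(genome$seq)
  A <- revcomp(genome$seq)

  # baseline: best unspliced antisense candidate
  uns <- enumerate_orfs(genome, table_id, start_codons, min_aa,
                        strands = "antisense")
  base_score <- -1L; base_len <- 0L
  if (nrow(uns) > 0L) {
    sc <- vapply(uns$protein,
                 function(p) rep_motif_score(p, patterns), integer(1))
    i <- order(-sc, -uns$aa_len)[1]
    base_score <- sc[i]; base_len <- uns$aa_len[i]
  }
  # a spliced candidate must strictly improve the motif score, so a
  # motif-complete unspliced Rep already rules out any intron
  if (base_score >= length(patterns)) return(NULL)

  # per-frame codon classification of A (linear)
  frames <- lapply(0:2, function(f) {
    starts <- seq.int(f + 1L, L - 2L, 3L)
    codons <- substring(A, starts, starts + 2L)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    list(starts = starts,
         stops = starts[aa == "*"],
         atg = starts[codons == "ATG"],
         alt = starts[codons %in% setdiff(start_codons, "ATG")],
         codons = codons, aa = aa)
  })
  first_geq <- function(v, x) { i <- findInterval(x - 1e-9, v) + 1L
                                if (i <= length(v)) v[i] else NA_integer_ }
  last_leq <- function(v, x) { i <- findInterval(x, v)
                               if (i >= 1L) v[i] else NA_integer_ }

  chars <- strsplit(A, "", fixed = TRUE)[[1]]
  gt <- which(chars[-L] == "G" & chars[-1L] == "T")            # donor start d
  ag_g <- which(chars[-1L] == "G" & chars[-L] == "A") + 1L     # acceptor end a

  best <- NULL
  for (d in gt) {
    amin <- d + 3L                 # intron length >= 4
    amax <- min(d + max_intron - 1L, L - 3L)
    if (amin > amax) next
    accs <- ag_g[ag_g >= amin & ag_g <= amax]
    for (a in accs) {
      for (f1 in 0:2) {
        nfull <- (d - 1L - f1) %/% 3L
        if (nfull < 1L) next
        leftover <- (d - 1L - f1) %% 3L
        lastfull <- f1 + 1L + 3L * (nfull - 1L)
        fr1 <- frames[[f1 + 1L]]
        # junction codon spanning the splice, if any
        if (leftover > 0L) {
          jcod <- paste0(substr(A, d - leftover, d - 1L),
                         substr(A, a + 1L, a + 3L - leftover))
          ja <- code[jcod]
          if (is.na(ja)) ja <- "X"
          if (ja == "*") next
          q0 <- a + 1L + (3L - leftover)
        } else q0 <- a + 1L
        if (q0 + 2L > L) next
        f2 <- (q0 - 1L) %% 3L
        fr2 <- frames[[f2 + 1L]]
        s_end <- first_geq(fr2$stops, q0)
        if (is.na(s_end)) next
        prevstop <- last_leq(fr1$stops, lastfull)
        lo <- if (is.na(prevstop)) f1 + 1L else prevstop + 3L
        p_s <- first_geq(fr1$atg, lo)
        if (is.na(p_s) || p_s > lastfull) {
          p_s <- first_geq(fr1$alt, lo)
          if (is.na(p_s) || p_s > lastfull) next
        }
        nt_total <- (d - p_s) + (s_end + 2L - a)
        aa_len <- nt_total %/% 3L - 1L
        if (aa_len < min_aa) next
        if (nt_total > L) next
        # assemble the protein from the precomputed per-frame translations
        i_s <- (p_s - f1 - 1L) %/% 3L + 1L
        i_last <- (lastfull - f1 - 1L) %/% 3L + 1L
        j0 <- (q0 - f2 - 1L) %/% 3L + 1L
        j_end <- (s_end - f2 - 1L) %/% 3L + 1L
        aa1 <- fr1$aa[i_s:i_last]
        aa1[1] <- "M"
        aa2 <- if (j_end > j0) fr2$aa[j0:(j_end - 1L)] else character()
        prot <- paste(c(aa1, if (leftover > 0L) ja, aa2), collapse = "")
        sc <- rep_motif_score(prot, patterns)
        if (is.null(best) || sc > best$score ||
            (sc == best$score && aa_len > best$aa_len)) {
          best <- list(score = sc, aa_len = aa_len, p_s = p_s, d = d, a = a,
                       s_end = s_end, protein = prot,
                       init_codon = substr(A, p_s, p_s + 2L))
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  # a spliced candidate must strictly improve the motif score: when the
  # unspliced Rep already carries all motifs, no intron is ever imputed
  if (best$score <= base_score) return(NULL)
  v <- function(q) L - q + 1L
  structure(list(
    strand = "antisense",
    segments = list(c(v(best$p_s), v(best$d - 1L)),
                    c(v(best$a + 1L), v(best$s_end + 2L))),
    intron = c(v(best$d), v(best$a)),
    start_nt = v(best$p_s), end_nt = v(best$s_end + 2L),
    init_codon = best$init_codon, table_id = as.integer(table_id),
    protein = best$protein, aa_len = best$aa_len,
    motif_score = best$score), class = "spliced_orf")
}

#' Assign Rep and Cp roles and compute intergenic regions
#'
#' Rep is the antisense candidate (spliced if provided) with the highest
#' conserved-motif score, ties broken by protein length; Cp is the
#' virion-sense ORF with the highest arginine-rich N-terminal score, ties
#' broken by length. The 5'-intergenic region spans the gap between the two
#' initiation codons and contains position one; the 3'-intergenic region is
#' the gap between the two stop codons on the opposite side, absent when the
#' ORFs abut or overlap.
#'
#' @param orfs data frame from \code{\link{enumerate_orfs}} (rotated genome).
#' @param spliced optional \code{spliced_orf} from
#'   \code{\link{find_spliced_rep}}.
#' @param genome the ori-rotated \code{\link{circular_genome}}.
#' @param patterns Rep motif patterns.
#' @param arg_window window (aa) for the arginine-rich score.
#' @return list with \code{rep}, \code{cp} (each an \code{orf_annotation}
#'   list or \code{NULL}), \code{ir5}, \code{ir3} (each \code{c(start, end)}
#'   or \code{NULL}) and \code{complete} flag.
#' @export
assign_roles <- function(orfs, spliced = NULL, genome,
                         patterns = default_rep_motif_patterns(),
                         arg_window = 20L) {
  L <- nchar(genome$seq)
  anti <- orfs[orfs$strand == "antisense", , drop = FALSE]
  sense <- orfs[orfs$strand == "sense", , drop = FALSE]

  rep_ann <- NULL
  cand <- list()
  if (nrow(anti) > 0L) {
    for (i in seq_len(nrow(anti))) {
      sc <- rep_motif_score(anti$protein[i], patterns)
      cand[[length(cand) + 1L]] <- orf_ann_from_row(anti[i, ], role = "rep",
                                                    motif_score = sc)
    }
  }
  if (!is.null(spliced)) {
    sp <- unclass(spliced)
    sp$role <- "rep"
    cand[[length(cand) + 1L]] <- sp
  }
  if (length(cand) > 0L) {
    scs <- vapply(cand, function(x) x$motif_score, numeric(1))
    lens <- vapply(cand, function(x) x$aa_len, numeric(1))
    rep_ann <- cand[[order(-scs, -lens)[1]]]
  }

  cp_ann <- NULL
  if (nrow(sense) > 0L) {
    args <- vapply(sense$protein, arg_rich_score, numeric(1),
                   window = arg_window)
    i <- order(-args, -sense$aa_len)[1]
    cp_ann <- orf_ann_from_row(sense[i, ], role = "cp",
                               arg_score = unname(args[i]))
  }

  ir5 <- ir3 <- NULL
  if (!is.null(rep_ann) && !is.null(cp_ann)) {
    # 5'-IR: between the initiation codons, containing position 1
    s_rep <- rep_ann$start_nt          # high virion position (antisense)
    s_cp <- cp_ann$start_nt            # low virion position (sense)
    ir5_start <- (s_rep %% L) + 1L
    ir5_end <- s_cp - 1L
    if (ir5_end < 1L) ir5_end <- L
    ir5 <- c(ir5_start, ir5_end)
    # 3'-IR: between the stop codons on the far side
    e_cp <- cp_ann$end_nt              # last nt of cp stop codon
    e_rep <- rep_ann$end_nt            # low virion end of rep (stop side)
    if (e_rep - e_cp >= 2L) ir3 <- c(e_cp + 1L, e_rep - 1L)
  }
  list(rep = rep_ann, cp = cp_ann, ir5 = ir5, ir3 = ir3,
       complete = !is.null(rep_ann) && !is.null(cp_ann))
}

# Convert one enumerate_orfs row into an orf annotation list.
orf_ann_from_row <- function(row, role = "other", motif_score = NA_real_,
                             arg_score = NA_real_) {
  list(role = role, strand = row$strand,
       segments = list(c(row$start_nt, row$end_nt)), intron = NULL,
       start_nt = row$start_nt, end_nt = row$end_nt,
       init_codon = row$init_codon, table_id = row$table_id,
       protein = row$protein, aa_len = row$aa_len,
       motif_score = motif_score, arg_score = arg_score)
}
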