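# Synthetic cyclovirus-like genome generator with fully known ground truth.

#' Specification for a synthetic cyclovirus-like genome
#'
#' Describes the architecture the generator plants: a nonanucleotide motif at
#' the apex of a stem-loop in the 5'-intergenic region, a virion-sense Cp ORF
#' with an arginine-rich amino terminus, an antisense Rep ORF carrying all
#' six conserved motifs under a chosen translation table and initiation
#' codon, optionally split by a canonical GT/AG intron, and an optional
#' 3'-intergenic region. Defaults emulate a typical 1.7-1.9 kb cyclovirus.
#'
#' @param genome_len total length in nt, or \code{NULL} to draw uniformly
#'   from 1700-1910 (floored at the minimum the features require).
#' @param motif 9-nt nonanucleotide motif to plant.
#' @param arm_len,loop_len stem arm and loop lengths (loop includes the
#'   motif).
#' @param rep_len_aa,cp_len_aa protein lengths (aa, stop excluded).
#' @param rep_table translation table for Rep (1, 4 or 5). Tables 4 and 5
#'   plant TGA-read-through tryptophans so the standard code cannot produce
#'   an intact Rep; table 5 additionally encodes a motif serine as AGA so
#'   table 4 translation breaks the Walker A motif.
#' @param rep_start_codon Rep initiation codon (\code{ATG}, \code{ATA},
#'   \code{TTG} or \code{GTG}).
#' @param intron_len intron length in nt (0 = unspliced). Lengths that are a
#'   multiple of 3 leave the unspliced reading in frame and make recovery
#'   ambiguous; the default 56 mirrors a small frame-shifting intron.
#' @param cp_arg_frac target R+K fraction in the Cp N-terminal window.
#' @param arg_window Cp N-terminal window size (aa).
#' @param ir3_len 3'-intergenic length in nt (0 = ORFs abut; the 3'-IR is
#'   then absent).
#' @return list of class \code{genome_spec}.
#' @export
genome_spec <- function(genome_len = NULL, motif = "TAGTATTAC",
                        arm_len = 8L, loop_len = 11L,
                        rep_len_aa = 280L, cp_len_aa = 258L,
                        rep_table = 1L, rep_start_codon = "ATG",
                        intron_len = 0L, cp_arg_frac = 0.55,
                        arg_window = 20L, ir3_len = 4L) {
  motif <- toupper(motif)
  if (nchar(motif) != 9L) stop("motif must be 9 nt")
  if (loop_len < 9L + 2L || loop_len > 13L) stop("loop_len must be 11..13")
  if (!rep_table %in% c(1L, 4L, 5L)) stop("rep_table must be 1, 4 or 5")
  rep_start_codon <- toupper(rep_start_codon)
  if (!rep_start_codon %in% c("ATG", "ATA", "TTG", "GTG")) {
    stop("unsupported rep_start_codon")
  }
  if (rep_table == 1L && rep_start_codon == "ATA") {
    stop("ATA cannot initiate under the standard code")
  }
  if (intron_len != 0L && intron_len < 6L) stop("intron_len must be 0 or >= 6")
  if (rep_len_aa < 100L || cp_len_aa < 100L) {
    stop("rep_len_aa and cp_len_aa must be >= 100")
  }
  structure(list(genome_len = genome_len, motif = motif,
                 arm_len = as.integer(arm_len), loop_len = as.integer(loop_len),
                 rep_len_aa = as.integer(rep_len_aa),
                 cp_len_aa = as.integer(cp_len_aa),
                 rep_table = as.integer(rep_table),
                 rep_start_codon = rep_start_codon,
                 intron_len = as.integer(intron_len),
                 cp_arg_frac = cp_arg_frac,
                 arg_window = as.integer(arg_window),
                 ir3_len = as.integer(ir3_len)), class = "genome_spec")
}

# run expr under a temporary RNG seed (NULL = use the current stream)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

# fixed codon encodings used by the generator
.gen_codons <- list(
  filler_aa = c("A", "E", "Q", "P", "H"),
  aa2codon = c(A = "GCC", E = "GAA", Q = "CAA", P = "CCT", H = "CAC",
               F = "TTC", T = "ACC", L = "CTT", N = "AAC", V = "GTC",
               G = "GGC", Y = "TAC", C = "TGC", S = "TCC", K = "AAA",
               D = "GAC", W = "TGG", R = "CGC"),
  rk = c("CGC", "CGT", "AAA", "AAG"))

# planted Rep motif instances (match the default degenerate patterns)
.rep_motif_instances <- c("RCR-I" = "FTLNN", "RCR-II" = "AHVQG",
                          "RCR-III" = "YCSK", "WalkerA" = "GPPGTGKS",
                          "WalkerB" = "LLFDD", "MotifC" = "LTSN")

# aa offsets (1-based) for planted motifs, scaled to protein length
rep_motif_offsets <- function(n) {
  off <- c("RCR-I" = max(5L, round(0.06 * n)),
           "RCR-II" = round(0.15 * n),
           "RCR-III" = round(0.30 * n),
           "WalkerA" = round(0.60 * n),
           "WalkerB" = round(0.75 * n),
           "MotifC" = round(0.88 * n))
  as.integer(off)
}

rand_bases <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# build a CDS (start codon through stop) for a given aa layout
build_cds <- function(n_aa, start_codon, planted, w_positions = integer(),
                      special = list(), rk_positions = integer()) {
  # planted: named list position -> aa string
  aa <- rep(NA_character_, n_aa)
  aa[1] <- "M"
  for (p in names(planted)) {
    pos <- as.integer(p)
    res <- strsplit(planted[[p]], "", fixed = TRUE)[[1]]
    aa[pos:(pos + length(res) - 1L)] <- res
  }
  for (p in w_positions) aa[p] <- "W"
  for (p in rk_positions) if (is.na(aa[p])) aa[p] <- "RK"
  fill <- is.na(aa)
  aa[fill] <- sample(.gen_codons$filler_aa, sum(fill), replace = TRUE)
  codons <- character(n_aa)
  for (i in seq_len(n_aa)) {
    codons[i] <- if (i == 1L) start_codon
      else if (aa[i] == "RK") sample(.gen_codons$rk, 1L)
      else .gen_codons$aa2codon[[aa[i]]]
  }
  for (p in names(special)) codons[as.integer(p)] <- special[[p]]
  paste(c(codons, "TAA"), collapse = "")
}

# intron with canonical GT..AG ends and no internal GT/AG dinucleotides
build_intron <- function(len) {
  repeat {
    inner <- strsplit(rand_bases(len - 4L), "", fixed = TRUE)[[1]]
    s <- c("G", "T", inner, "A", "G")
    di <- paste0(s[-length(s)], s[-1L])
    bad <- which(di %in% c("GT", "AG"))
    bad <- setdiff(bad, c(1L, length(di)))
    if (length(bad) == 0L) return(paste(s, collapse = ""))
  }
}

#' Generate a synthetic cyclovirus-like genome with ground truth
#'
#' Assembles a circular genome following the planted architecture of the
#' spec, applies a random rotation and (optionally) strand flip, and returns
#' the emitted genome together with the truth needed to verify every
#' annotation stage. Non-feature sequence is resampled until the planted
#' nonanucleotide motif is the genome's unique hit at one mismatch.
#'
#' @param spec a \code{\link{genome_spec}}.
#' @param seed RNG seed (\code{NULL} uses the current stream).
#' @param id genome label.
#' @param random_orientation apply a random rotation and strand flip
#'   (default \code{TRUE}).
#' @return list with \code{genome} (the emitted \code{circular_genome}) and
#'   \code{truth}, a list holding the canonical (ori-rotated, virion-sense)
#'   sequence and feature coordinates in canonical coordinates: \code{cp}
#'   and \code{rep} regions, \code{rep_segments}, \code{intron}, \code{ir5},
#'   \code{ir3}, \code{rep_table}, \code{rep_start_codon},
#'   \code{rep_protein}, \code{cp_protein}, \code{motif_aa_pos},
#'   \code{rotation_offset}, \code{flipped}.
#' @export
generate_genome <- function(spec = genome_spec(), seed = NULL,
                            id = "synthetic", random_orientation = TRUE) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(seed, {
    loop_pre <- 1L
    loop_post <- spec$loop_len - 9L - loop_pre
    cp_nt <- 3L * (spec$cp_len_aa + 1L)
    rep_nt <- 3L * (spec$rep_len_aa + 1L) + spec$intron_len
    fixed <- 9L + loop_post + loop_pre + 2L * spec$arm_len + 6L +
      cp_nt + spec$ir3_len + rep_nt
    gl <- spec$genome_len
    if (is.null(gl)) gl <- sample(max(1700L, fixed + 20L):1910L, 1L)
    spacer_total <- gl - fixed
    if (spacer_total < 2L) {
      stop("infeasible spec: features need ", fixed + 2L,
           " nt but genome_len is ", gl)
    }

    # Rep protein layout
    n <- spec$rep_len_aa
    offs <- rep_motif_offsets(n)
    planted <- as.list(.rep_motif_instances)
    names(planted) <- as.character(offs)
    w_pos <- integer()
    special <- list()
    if (spec$rep_table %in% c(4L, 5L)) {
      w_pos <- c(offs[2] + 6L, offs[5] + 6L)   # TGA read-through tryptophans
    }
    if (spec$rep_table == 5L) {
      # Walker A terminal serine encoded as AGA: Ser only under table 5
      special[[as.character(offs[4] + 7L)]] <- "AGA"
    }

    for (attempt in 1:80) {
      rep_cds <- build_cds(n, spec$rep_start_codon, planted, w_pos, special)
      if (spec$intron_len > 0L) {
        # insert between the RCR block and the helicase block, on a codon
        # boundary chosen at random
        lo <- offs[3] + 6L; hi <- offs[4] - 2L
        cb <- sample(lo:hi, 1L)
        e1 <- 3L * cb
        intron <- build_intron(spec$intron_len)
        rep_cds_g <- paste0(substr(rep_cds, 1L, e1), intron,
                            substr(rep_cds, e1 + 1L, nchar(rep_cds)))
      } else {
        e1 <- NA_integer_; intron <- NULL; rep_cds_g <- rep_cds
      }

      # Cp with exact R+K count in the N-terminal window
      w <- min(spec$arg_window, spec$cp_len_aa)
      n_rk <- round(spec$cp_arg_frac * w)
      n_rk <- min(n_rk, w - 1L)
      rk_positions <- sample(2:w, n_rk)
      cp_cds <- build_cds(spec$cp_len_aa, "ATG", planted = list(),
                          rk_positions = rk_positions)

      sA <- sample(1:(spacer_total - 1L), 1L)
      sB <- spacer_total - sA
      arm3 <- rand_bases(spec$arm_len)
      parts <- c(spec$motif, rand_bases(loop_post), arm3, rand_bases(sA),
                 "TAA", cp_cds, rand_bases(spec$ir3_len),
                 revcomp(rep_cds_g), "TTA", rand_bases(sB),
                 revcomp(arm3), rand_bases(loop_pre))
      canonical <- paste(parts, collapse = "")
      stopifnot(nchar(canonical) == gl)
      g <- circular_genome(id, canonical)
      hits <- find_nonanucleotide(g, "NAGTATTAC", 1L)
      ok <- nrow(hits) == 1L && hits$strand[1] == "sense" &&
        hits$start_nt[1] == 1L
      if (ok) break
      if (attempt == 80L) stop("could not generate an unambiguous genome; ",
                               "try another seed")
    }

    cp_start <- 9L + loop_post + spec$arm_len + sA + 3L + 1L
    cp_end <- cp_start + cp_nt - 1L
    gstart <- cp_end + spec$ir3_len + 1L
    gend <- gstart + rep_nt - 1L
    if (spec$intron_len > 0L) {
      i0 <- e1 + 1L
      intron_coords <- c(gend - i0 + 1L, gend - (i0 + spec$intron_len - 1L) + 1L)
      segs <- list(c(gend, gend - e1 + 1L),
                   c(gend - e1 - spec$intron_len, gstart))
    } else {
      intron_coords <- NULL
      segs <- list(c(gend, gstart))
    }

    truth <- list(
      canonical_seq = canonical,
      genome_len = gl,
      motif = spec$motif,
      cp = c(cp_start, cp_end),
      rep = c(gend, gstart),
      rep_segments = segs,
      intron = intron_coords,
      ir5 = c((gend %% gl) + 1L, cp_start - 1L),
      ir3 = if (spec$ir3_len > 0L) c(cp_end + 1L, cp_end + spec$ir3_len)
            else NULL,
      rep_table = spec$rep_table,
      rep_start_codon = spec$rep_start_codon,
      rep_protein = translate_cds(rep_cds, spec$rep_table),
      cp_protein = translate_cds(cp_cds, spec$rep_table),
      motif_aa_pos = stats::setNames(offs, names(.rep_motif_instances)),
      cp_arg_frac_target = n_rk / w,
      rotation_offset = 1L, flipped = FALSE)

    out <- g
    if (random_orientation) {
      r <- sample.int(gl, 1L)
      out <- rotate(g, r)
      truth$rotation_offset <- r
      if (stats::runif(1) < 0.5) {
        out <- circular_genome(id, revcomp(out$seq))
        truth$flipped <- TRUE
      }
    }
    list(genome = out, truth = truth)
  })
}

#' Apply independent per-site substitutions to a genome
#'
#' Each site mutates with probability \code{rate} to a uniformly chosen
#' different base, so the expected fraction of differing sites equals
#' \code{rate}.
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param rate per-site substitution probability in [0, 0.75].
#' @param seed RNG seed (\code{NULL} uses the current stream).
#' @return mutated \code{circular_genome}.
#' @export
mutate_genome <- function(genome, rate, seed = NULL) {
  stopifnot(inherits(genome, "circular_genome"))
  if (rate < 0 || rate > 0.75) stop("rate must be in [0, 0.75]")
  with_seed(seed, {
    chars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(chars)) < rate)
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
    circular_genome(genome$id, paste(chars, collapse = ""), genome$topology)
  })
}

#' Generate a panel of synthetic species with known partition
#'
#' Species founders are independent heavily mutated copies of one base
#' genome; members within a species are lightly mutated copies of their
#' founder, so within-species identities sit far above the demarcation
#' threshold and between-species identities far below it.
#'
#' @param n_species number of species.
#' @param per_species members per species (scalar or vector).
#' @param within_rate per-site substitution rate within species.
#' @param between_rate rate separating founders (must exceed
#'   \code{within_rate}).
#' @param seed RNG seed.
#' @param spec base \code{\link{genome_spec}}.
#' @return list with \code{genomes} (named list of
#'   \code{circular_genome}s), \code{truth} (named integer species
#'   partition).
#' @export
generate_species_panel <- function(n_species = 2L, per_species = 2L,
                                   within_rate = 0.002, between_rate = 0.35,
                                   seed = NULL, spec = genome_spec()) {
  if (within_rate >= between_rate) {
    stop("within_rate must be below between_rate")
  }
  with_seed(seed, {
    if (length(per_species) == 1L) {
      per_species <- rep(per_species, n_species)
    }
    stopifnot(length(per_species) == n_species)
    base <- generate_genome(spec, seed = NULL, id = "base",
                            random_orientation = FALSE)$genome
    genomes <- list()
    truth <- integer()
    for (s in seq_len(n_species)) {
      founder <- mutate_genome(base, between_rate)
      for (j in seq_len(per_species[s])) {
        lab <- sprintf("S%d_%d", s, j)
        g <- if (j == 1L) founder else mutate_genome(founder, within_rate)
        g$id <- lab
        genomes[[lab]] <- g
        truth[lab] <- s
      }
    }
    list(genomes = genomes, truth = truth)
  })
}
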