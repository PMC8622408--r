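# Global pairwise alignment, identity matrices, and ICTV-style genus/species
# demarcation.

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch-style optimal global alignment via
#' \code{Biostrings::pairwiseAlignment}. Nucleotide scoring defaults to
#' match +5 / mismatch -4 with gap open 10 and extension 0.5; \code{N}
#' mismatches every base, including \code{N}. Amino-acid scoring uses
#' BLOSUM62 with the same gap penalties.
#'
#' @param a,b sequences (character strings of the same alphabet class).
#' @param alphabet \code{"auto"} (default), \code{"nt"} or \code{"aa"}.
#' @param match,mismatch nucleotide scores.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return list of class \code{pairwise_alignment}: \code{a}, \code{b}
#'   (gapped strings), \code{score}, \code{alphabet}.
#' @export
global_align <- function(a, b, alphabet = c("auto", "nt", "aa"),
                         match = 5, mismatch = -4,
                         gap_open = 10, gap_extend = 0.5) {
  alphabet <- match.arg(alphabet)
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  looks_nt <- function(s) !grepl("[^ACGTUN]", s)
  if (alphabet == "auto") {
    na_ <- looks_nt(a); nb_ <- looks_nt(b)
    if (na_ != nb_) stop("mixed alphabets: one sequence looks nucleotide, ",
                         "the other amino acid")
    alphabet <- if (na_) "nt" else "aa"
  }
  if (alphabet == "nt") {
    a <- chartr("U", "T", a); b <- chartr("U", "T", b)
    bases <- c("A", "C", "G", "T", "N")
    sm <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
    diag(sm) <- match
    sm["N", ] <- mismatch; sm[, "N"] <- mismatch   # N matches nothing
    aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = sm,
                                         gapOpening = gap_open,
                                         gapExtension = gap_extend)
  } else {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = get("BLOSUM62", envir = environment()),
      gapOpening = gap_open, gapExtension = gap_extend)
  }
  structure(list(a = as.character(Biostrings::pattern(aln)),
                 b = as.character(Biostrings::subject(aln)),
                 score = Biostrings::score(aln),
                 alphabet = alphabet), class = "pairwise_alignment")
}

#' Percent identity of a pairwise alignment
#'
#' Default ("sdt") gap policy: identical residue pairs divided by all
#' alignment columns except those gapped in both sequences and terminal-gap
#' columns; gap-versus-residue columns inside the alignment count in the
#' denominator. \code{"exclude_gaps"} counts residue-residue columns only.
#' For nucleotides, \code{N} never matches.
#'
#' @param aln a \code{pairwise_alignment} from \code{\link{global_align}},
#'   or a list with gapped strings \code{a} and \code{b}.
#' @param mode gap-column policy.
#' @return identity as a percentage in [0, 100].
#' @export
pairwise_identity <- function(aln, mode = c("sdt", "exclude_gaps")) {
  mode <- match.arg(mode)
  pa <- strsplit(aln$a, "", fixed = TRUE)[[1]]
  pb <- strsplit(aln$b, "", fixed = TRUE)[[1]]
  if (length(pa) != length(pb)) stop("gapped strings differ in length")
  n <- length(pa)
  gap_a <- pa == "-"; gap_b <- pb == "-"
  keep <- !(gap_a & gap_b)
  # terminal gap columns: inside the leading/trailing gap run of either seq
  lead <- 0L
  while (lead < n && (gap_a[lead + 1L] || gap_b[lead + 1L])) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && (gap_a[n - trail] || gap_b[n - trail]))
    trail <- trail + 1L
  if (lead > 0L) keep[seq_len(lead)] <- FALSE
  if (trail > 0L) keep[(n - trail + 1L):n] <- FALSE
  if (mode == "exclude_gaps") keep <- keep & !gap_a & !gap_b
  denom <- sum(keep)
  if (denom == 0L) return(0)
  ident <- pa == pb & !gap_a & keep
  nt <- is.null(aln$alphabet) || identical(aln$alphabet, "nt")
  if (nt) ident <- ident & pa != "N"
  100 * sum(ident) / denom
}

#' Pairwise identity matrix for labeled sequences
#'
#' @param seqs named character vector (or named list of strings) of
#'   nucleotide or amino-acid sequences. Genome-level comparisons should use
#'   ori-rotated virion-sense sequences so linearization is consistent.
#' @param level stored as an attribute: \code{"genome-nt"}, \code{"rep-aa"}
#'   or \code{"cp-aa"}.
#' @param mode gap policy for \code{\link{pairwise_identity}}.
#' @param ... scoring parameters passed to \code{\link{global_align}}.
#' @return symmetric matrix of percent identities (diagonal 100) with class
#'   \code{identity_matrix} and attribute \code{level}.
#' @export
identity_matrix <- function(seqs, level = "genome-nt", mode = "sdt", ...) {
  seqs <- unlist(seqs)
  if (length(seqs) < 2L) stop("need >= 2 sequences")
  labs <- names(seqs)
  if (is.null(labs) || anyNA(labs) || any(!nzchar(labs))) {
    stop("sequences must be named")
  }
  if (anyDuplicated(labs)) stop("duplicate sequence labels")
  k <- length(seqs)
  m <- matrix(100, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      aln <- global_align(seqs[[i]], seqs[[j]], ...)
      m[i, j] <- m[j, i] <- pairwise_identity(aln, mode)
    }
  }
  structure(m, level = level, class = c("identity_matrix", "matrix", "array"))
}

#' Species demarcation by single-linkage clustering
#'
#' Two sequences share a species cluster iff they are connected by a chain of
#' pairwise identities at or above the threshold (ICTV convention: genomes
#' sharing < 80 percent genome-wide identity belong to distinct species).
#'
#' @param m identity matrix (symmetric, percent).
#' @param threshold percent identity threshold (default 80).
#' @return list of class \code{species_assignment}: \code{threshold},
#'   \code{clusters} (named integer vector, cluster ids in order of first
#'   appearance), \code{n_clusters}.
#' @export
demarcate_species <- function(m, threshold = 80) {
  m <- unclass(as.matrix(m))
  labs <- rownames(m)
  k <- nrow(m)
  comp <- rep(NA_integer_, k)
  cid <- 0L
  for (i in seq_len(k)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(m[v, ] >= threshold & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  names(comp) <- labs
  structure(list(threshold = threshold, clusters = comp,
                 n_clusters = max(comp)), class = "species_assignment")
}

#' @export
print.species_assignment <- function(x, ...) {
  cat(sprintf("<species_assignment> %d cluster(s) at >= %s%% identity\n",
              x$n_clusters, format(x$threshold)))
  for (k in seq_len(x$n_clusters)) {
    cat(sprintf("  species %d: %s\n", k,
                paste(names(x$clusters)[x$clusters == k], collapse = ", ")))
  }
  invisible(x)
}

#' Genus-level classification of an annotated genome
#'
#' Evaluates the criteria used to call a CRESS DNA genome cyclovirus-like:
#' ori on the Cp-encoding strand within the 5'-intergenic region, genome-wide
#' identity above the genus threshold to reference cycloviruses, a
#' motif-complete Rep, and an arginine-rich Cp N-terminus. The cyclovirus
#' call requires the ori criterion plus at least one other positive
#' criterion; a genome whose motif lies on the Rep-encoding strand is called
#' circovirus-like; no motif yields unclassified.
#'
#' @param annotation a \code{genome_annotation} from
#'   \code{\link{annotate_genome}}.
#' @param refs optional named character vector of reference cyclovirus
#'   genome sequences (ori-rotated) for the identity criterion.
#' @param genus_threshold percent genome identity supporting genus
#'   membership (default 55).
#' @param arg_threshold minimum arginine-rich score counted as positive.
#' @param phylo_support optional logical flag from a phylogenetic analysis.
#' @return list of class \code{genus_call}: \code{call} and \code{evidence}
#'   (named logical vector).
#' @export
classify_genus <- function(annotation, refs = NULL, genus_threshold = 55,
                           arg_threshold = 0.3, phylo_support = NA) {
  ev <- c(ori_on_cp_strand = FALSE, identity_over_genus_threshold = NA,
          motif_complete_rep = FALSE, arg_rich_cp = FALSE,
          phylogenetic_support = phylo_support)
  if (is.null(annotation$ori)) {
    return(structure(list(call = "unclassified", evidence = ev),
                     class = "genus_call"))
  }
  cp <- annotation$cp
  rep_ <- annotation$rep
  # after rotation the motif sits on the virion-sense strand; cyclovirus
  # organization means the motif-bearing (antisense-coded) Rep faces a
  # sense-strand Cp, circovirus organization means Rep itself is on the
  # motif strand
  anti_rep_score <- if (is.null(rep_)) -1 else rep_$motif_score
  sense_rep_score <- if (is.null(annotation$sense_rep_score)) -1 else
    annotation$sense_rep_score
  ori_cp_strand <- !is.null(cp) && cp$strand == "sense" &&
    anti_rep_score >= sense_rep_score
  ori_rep_strand <- sense_rep_score > anti_rep_score
  ev["ori_on_cp_strand"] <- isTRUE(ori_cp_strand)
  if (!is.null(rep_)) {
    ev["motif_complete_rep"] <- isTRUE(rep_$motif_score ==
                                         annotation$n_motifs_expected)
  }
  if (!is.null(cp) && !is.na(cp$arg_score)) {
    ev["arg_rich_cp"] <- cp$arg_score >= arg_threshold
  }
  if (!is.null(refs) && length(refs) > 0L) {
    ids <- vapply(refs, function(r) {
      pairwise_identity(global_align(annotation$genome$seq, r))
    }, numeric(1))
    ev["identity_over_genus_threshold"] <- max(ids) > genus_threshold
  }
  pos_other <- sum(c(isTRUE(ev["identity_over_genus_threshold"]),
                     isTRUE(ev["motif_complete_rep"]),
                     isTRUE(ev["arg_rich_cp"]),
                     isTRUE(ev["phylogenetic_support"])))
  call <- if (ev["ori_on_cp_strand"] && pos_other >= 1L) "cyclovirus-like"
          else if (isTRUE(ori_rep_strand)) "circovirus-like"
          else "unclassified"
  structure(list(call = call, evidence = ev), class = "genus_call")
}

#' Write / read an identity matrix as TSV
#'
#' Labels in the first row and first column.
#'
#' @param m identity matrix.
#' @param path file path.
#' @return \code{path} (write) or an \code{identity_matrix} (read).
#' @export
write_identity_tsv <- function(m, path) {
  df <- cbind(label = rownames(m), as.data.frame(unclass(as.matrix(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_identity_tsv
#' @param level level attribute for the matrix read back.
#' @export
read_identity_tsv <- function(path, level = "genome-nt") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (!isTRUE(all.equal(unname(m), unname(t(m)), tolerance = 1e-8))) {
    stop("matrix in ", path, " is not symmetric")
  }
  structure(m, level = level, class = c("identity_matrix", "matrix", "array"))
}
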