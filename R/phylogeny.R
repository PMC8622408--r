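# Distance-based phylogeny: neighbor-joining with bootstrap, plus a
# sliding-window identity screen.

#' Distance matrix from an identity matrix
#'
#' @param m identity matrix (percent).
#' @return symmetric distance matrix \code{(100 - identity)/100}.
#' @export
identity_to_dist <- function(m) {
  d <- (100 - unclass(as.matrix(m))) / 100
  diag(d) <- 0
  d
}

#' Neighbor-joining tree
#'
#' Wraps \code{ape::nj}; negative branch lengths (an NJ artifact) are clamped
#' to zero with the deficit shifted to the sibling edge, preserving path
#' lengths through the parent node.
#'
#' @param d symmetric distance matrix (or \code{dist}) over >= 3 labels.
#' @return an unrooted \code{ape::phylo} tree.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3L) stop("neighbor-joining needs >= 3 labels")
  tr <- ape::nj(as.dist(m))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs) > 0L) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + deficit
    }
    tr$edge.length[e] <- 0
  }
  tr
}

# p-distance matrix from a character matrix of aligned sequences (rows=taxa)
aligned_pdist <- function(mat) {
  k <- nrow(mat)
  d <- matrix(0, k, k, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      d[i, j] <- d[j, i] <- if (any(ok))
        mean(mat[i, ok] != mat[j, ok]) else 0
    }
  }
  d
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds an NJ tree from p-distances over an alignment and attaches percent
#' bootstrap support (column resampling) to internal nodes. Deterministic
#' given \code{seed}.
#'
#' @param seqs named character vector of aligned sequences (equal lengths,
#'   gaps as \code{"-"}).
#' @param replicates bootstrap replicates (default 100; 0 returns the tree
#'   without supports).
#' @param seed RNG seed.
#' @return an \code{ape::phylo} tree; when \code{replicates > 0},
#'   \code{node.label} holds percent support.
#' @export
bootstrap_support <- function(seqs, replicates = 100L, seed = 1L) {
  if (length(seqs) < 3L) stop("need >= 3 sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must be aligned")
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  # canonical taxon order so supports do not depend on input label order
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  tr <- nj_tree(aligned_pdist(mat))
  if (replicates <= 0L) return(tr)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  counts <- ape::boot.phylo(tr, mat,
                            FUN = function(x) nj_tree(aligned_pdist(x)),
                            B = replicates, rooted = FALSE, quiet = TRUE)
  tr$node.label <- round(100 * counts / replicates, 1)
  tr
}

#' Sliding-window identity profile
#'
#' Percent identity of a query genome against each reference over sliding
#' windows, by global alignment per window. Genomes should be rotated to the
#' ori so windows are comparable. A lightweight visual screen for mosaic
#' (recombinant-like) structure.
#'
#' @param query a \code{\link{circular_genome}}.
#' @param refs named list of \code{circular_genome}s (or named character
#'   vector of sequences).
#' @param window window size in nt (values < 50 warn: noisy).
#' @param step step size in nt.
#' @return data frame \code{window_start}, \code{ref}, \code{identity}.
#' @export
sliding_window_identity <- function(query, refs, window = 200L, step = 50L) {
  qs <- if (inherits(query, "circular_genome")) query$seq else
    normalize_dna(query)
  if (window < 50L) warning("window < 50 nt gives noisy identity profiles")
  rseqs <- vapply(refs, function(r)
    if (inherits(r, "circular_genome")) r$seq else normalize_dna(r),
    character(1))
  if (is.null(names(rseqs))) stop("refs must be named")
  L <- nchar(qs)
  if (window > L) stop("window exceeds query length")
  starts <- seq.int(1L, L - window + 1L, step)
  out <- list()
  for (rn in names(rseqs)) {
    rl <- nchar(rseqs[[rn]])
    for (s in starts) {
      e <- s + window - 1L
      if (e > rl) next
      aln <- global_align(substr(qs, s, e), substr(rseqs[[rn]], s, e))
      out[[length(out) + 1L]] <- data.frame(
        window_start = s, ref = rn,
        identity = pairwise_identity(aln), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
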