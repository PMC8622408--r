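#' Construct a circular genome object
#'
#' A \code{circular_genome} is a named DNA sequence over \code{{A,C,G,T,N}}
#' with an explicit topology. Coordinates are 1-based inclusive on the
#' virion-sense strand throughout the package; antisense features are written
#' with \code{start > end} ("nt 1541--nt 846" style), reading descending.
#'
#' @param id character label for the record.
#' @param seq DNA sequence; lowercase and \code{U} are normalized, any other
#'   non-\code{ACGTN} character is an error.
#' @param topology \code{"circular"} (default) or \code{"linear"}.
#' @return An object of class \code{circular_genome} with fields \code{id},
#'   \code{seq} and \code{topology}.
#' @export
circular_genome <- function(id, seq, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  seq <- normalize_dna(seq, id = id)
  structure(list(id = as.character(id), seq = seq, topology = topology),
            class = "circular_genome")
}

# Uppercase, U->T, validate alphabet. Reports record id and first bad offset.
normalize_dna <- function(seq, id = "<sequence>") {
  seq <- toupper(as.character(seq))
  seq <- chartr("U", "T", seq)
  if (!nzchar(seq)) stop("empty sequence in record '", id, "'")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("invalid character '", substr(seq, bad, bad), "' at offset ", bad,
         " in record '", id, "'")
  }
  seq
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d nt (%s)\n", x$id, nchar(x$seq),
              x$topology))
  invisible(x)
}

#' @export
length.circular_genome <- function(x) nchar(x$seq)

#' Read genomes from a FASTA file
#'
#' @param path path to a FASTA file.
#' @param topology topology assigned to every record (default circular).
#' @return list of \code{\link{circular_genome}} objects, in file order.
#' @export
read_fasta <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- circular_genome(ids[i], as.character(set[[i]]), topology)
  }
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes a \code{circular_genome} or list of them.
#' @param path output path.
#' @param width line width (default 70).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "circular_genome")) genomes <- list(genomes)
  seqs <- vapply(genomes, function(g) g$seq, character(1))
  ids <- vapply(genomes, function(g) g$id, character(1))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read sequences from a GenBank flat file (sequence only)
#'
#' Parses only LOCUS/ORIGIN blocks; feature tables are ignored.
#'
#' @param path path to a GenBank flat file.
#' @param topology topology assigned to every record.
#' @return list of \code{\link{circular_genome}} objects.
#' @export
read_genbank <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines)
  if (length(locus) == 0L) stop("no LOCUS line in ", path)
  ends <- c(locus[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(locus)) {
    block <- lines[locus[k]:ends[k]]
    id <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    oi <- grep("^ORIGIN", block)
    if (length(oi) == 0L) stop("record '", id, "' has no ORIGIN block")
    body <- block[(oi[1] + 1L):length(block)]
    body <- body[!grepl("^//", body)]
    seq <- gsub("[0-9 ]", "", paste(body, collapse = ""))
    out[[id]] <- circular_genome(id, seq, topology)
  }
  out
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over \code{{A,C,G,T,N}} (case-insensitive).
#' @return the reverse complement; \code{N} maps to \code{N}.
#' @export
revcomp <- function(seq) {
  seq <- normalize_dna(seq)
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Rotate a circular genome to a new origin
#'
#' @param genome a \code{\link{circular_genome}} with circular topology.
#' @param new_start 1-based position that becomes position one.
#' @return a rotated \code{circular_genome}; \code{rotate(g, 1)} is \code{g}.
#' @export
rotate <- function(genome, new_start) {
  stopifnot(inherits(genome, "circular_genome"))
  if (genome$topology != "circular") stop("cannot rotate a linear genome")
  L <- nchar(genome$seq)
  new_start <- as.integer(new_start)
  if (new_start < 1L || new_start > L) stop("new_start out of range 1..", L)
  if (new_start == 1L) return(genome)
  g <- genome
  g$seq <- paste0(substr(genome$seq, new_start, L),
                  substr(genome$seq, 1L, new_start - 1L))
  g
}

#' Length of a genome region on a circular sequence
#'
#' Regions are 1-based inclusive in virion-sense coordinates. On the
#' virion-sense strand a region with \code{start > end} wraps the origin; on
#' the antisense strand \code{start > end} is the normal descending reading
#' and \code{start < end} wraps.
#'
#' @param start,end 1-based positions.
#' @param genome_len genome length in nt.
#' @param strand \code{"sense"} or \code{"antisense"}.
#' @return region length in nt (always >= 1).
#' @export
region_length <- function(start, end, genome_len, strand = "sense") {
  if (strand == "antisense") {
    ((start - end) %% genome_len) + 1L
  } else {
    ((end - start) %% genome_len) + 1L
  }
}

#' Extract the sequence of a region, strand-aware
#'
#' Antisense regions return the reverse complement, i.e. the sequence as read
#' by the ribosome, 5' to 3' on the coding strand.
#'
#' @inheritParams region_length
#' @param genome a \code{\link{circular_genome}}.
#' @return DNA string of the region.
#' @export
region_seq <- function(genome, start, end, strand = "sense") {
  L <- nchar(genome$seq)
  if (strand == "antisense") {
    # read descending start..end on virion numbering, then complement
    n <- region_length(start, end, L, "antisense")
    idx <- ((start - seq_len(n)) %% L) + 1L
    fwd <- paste(strsplit(genome$seq, "", fixed = TRUE)[[1]][idx],
                 collapse = "")
    chartr("ACGT", "TGCA", fwd)
  } else {
    n <- region_length(start, end, L, "sense")
    idx <- ((start + seq_len(n) - 2L) %% L) + 1L
    paste(strsplit(genome$seq, "", fixed = TRUE)[[1]][idx], collapse = "")
  }
}
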