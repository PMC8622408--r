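#' Genetic code table for a translation table id
#'
#' Supported tables: 1 (standard), 4 (mold/protozoan mitochondrial),
#' 5 (invertebrate mitochondrial). Table 5 renders ATA as Met, AGA/AGG as Ser
#' and TGA as Trp; table 4 renders TGA as Trp only. Stops are \code{"*"}.
#'
#' @param table_id 1, 4 or 5.
#' @return named character vector mapping the 64 codons to amino acids.
#' @export
genetic_code <- function(table_id) {
  table_id <- as.integer(table_id)
  if (!table_id %in% c(1L, 4L, 5L)) stop("unsupported translation table: ",
                                         table_id)
  key <- as.character(table_id)
  hit <- .code_cache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- Biostrings::getGeneticCode(key)
  names(gc) <- chartr("U", "T", names(gc))
  .code_cache[[key]] <- gc
  gc
}

.code_cache <- new.env(parent = emptyenv())

#' Translate a coding sequence
#'
#' @param cds DNA string; length must be a multiple of 3 and at least 6, and
#'   the final codon must be a stop under \code{table_id}.
#' @param table_id translation table (1, 4 or 5).
#' @param init_as_met render the first codon as \code{M} regardless of its
#'   elongation meaning (initiator tRNA behaviour); default \code{TRUE}.
#' @return amino-acid string without the terminal stop.
#' @export
translate_cds <- function(cds, table_id = 1L, init_as_met = TRUE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 6L || n %% 3L != 0L) {
    stop("CDS length must be a multiple of 3 and >= 6 (got ", n, ")")
  }
  code <- genetic_code(table_id)
  codons <- substring(cds, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  k <- length(aa)
  if (aa[k] != "*") stop("terminal codon '", codons[k],
                         "' is not a stop under table ", table_id)
  internal <- which(aa[-k] == "*")
  if (length(internal) > 0L) {
    stop("internal stop codon at codon index ", internal[1],
         " under table ", table_id)
  }
  if (init_as_met) aa[1] <- "M"
  paste(aa[-k], collapse = "")
}

#' Count amino-acid mismatches between two genetic-code translations
#'
#' Translates the same coding region under two translation tables and returns
#' the Hamming distance between the resulting proteins (which must have equal
#' length).
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param start,end region bounds (1-based inclusive virion coordinates;
#'   \code{start > end} with \code{strand = "antisense"} reads descending).
#' @param strand \code{"sense"} or \code{"antisense"}.
#' @param tables length-2 vector of table ids (default \code{c(1, 5)}).
#' @return integer count of differing residues.
#' @export
compare_code_translations <- function(genome, start, end, strand = "sense",
                                      tables = c(1L, 5L)) {
  stopifnot(length(tables) == 2L)
  cds <- region_seq(genome, start, end, strand)
  p1 <- translate_cds(cds, tables[1])
  p2 <- translate_cds(cds, tables[2])
  if (nchar(p1) != nchar(p2)) stop("translations differ in length")
  sum(strsplit(p1, "", fixed = TRUE)[[1]] !=
      strsplit(p2, "", fixed = TRUE)[[1]])
}

#' Default start-codon set
#'
#' ATG plus the alternative initiators seen in CRESS DNA virus annotation
#' (ATA, TTG, GTG). The set defines membership; the 5'-most occurrence wins
#' when no ATG is present.
#'
#' @return character vector of codons.
#' @export
default_start_codons <- function() c("ATG", "ATA", "TTG", "GTG")
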