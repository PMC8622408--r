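# Conserved Rep motif detection and Cp arginine-rich scoring.

#' Default degenerate consensus patterns for cyclovirus Rep motifs
#'
#' Rolling-circle replication endonuclease motifs I-III and superfamily 3
#' helicase motifs (Walker A, Walker B, motif C), as degenerate consensus
#' patterns drawn from the circovirus/CRESS literature. Each is a regular
#' expression over the amino-acid alphabet and can be overridden.
#'
#' @return named character vector of six patterns.
#' @export
default_rep_motif_patterns <- function() {
  c("RCR-I"   = "[FW]T[LIV]NN",
    "RCR-II"  = ".[HPA][LIV][QH]G",
    "RCR-III" = "Y[CLV][SK]K",
    "WalkerA" = "G[PIAK][PST]GTGKS",
    "WalkerB" = "[LIVM][LIVM][FD]DD",
    "MotifC"  = "[LIVM]T[SN]N")
}

#' Scan a Rep protein for conserved motifs
#'
#' Reports, for each motif, the leftmost match within its expected zone:
#' RCR motifs in the N-terminal half, helicase motifs in the C-terminal half
#' (zones can be disabled). The score counts distinct motifs found (0-6 with
#' the default set).
#'
#' @param protein amino-acid string.
#' @param patterns named character vector of regex patterns
#'   (default \code{\link{default_rep_motif_patterns}}).
#' @param zones restrict RCR motifs to the N-half and SF3 motifs to the
#'   C-half of the protein (default \code{TRUE}).
#' @return list of class \code{motif_profile}: \code{hits} (data frame
#'   \code{name}, \code{aa_start}, \code{matched}), \code{score},
#'   \code{ordered} (hits occur in canonical N-to-C order).
#' @export
scan_rep_motifs <- function(protein, patterns = default_rep_motif_patterns(),
                            zones = TRUE) {
  if (!nzchar(protein)) stop("empty protein")
  n <- nchar(protein)
  half <- n %/% 2L
  sf3 <- grepl("^(Walker|MotifC)", names(patterns))
  hits <- list()
  for (i in seq_along(patterns)) {
    if (zones && n >= 2L) {
      if (sf3[i]) { from <- half + 1L; to <- n } else { from <- 1L; to <- half }
    } else { from <- 1L; to <- n }
    sub <- substr(protein, from, to)
    m <- regexpr(patterns[i], sub, perl = TRUE)
    if (m > 0L) {
      hits[[length(hits) + 1L]] <- data.frame(
        name = names(patterns)[i],
        aa_start = as.integer(m) + from - 1L,
        matched = substr(sub, m, m + attr(m, "match.length") - 1L),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(name = character(), aa_start = integer(),
               matched = character(), stringsAsFactors = FALSE)
  structure(list(
    hits = hits,
    score = length(unique(hits$name)),
    ordered = !is.unsorted(hits$aa_start)), class = "motif_profile")
}

# fast motif count for scoring loops (no hit table construction)
rep_motif_score <- function(protein, patterns = default_rep_motif_patterns(),
                            zones = TRUE) {
  n <- nchar(protein)
  if (n < 2L) return(0L)
  half <- n %/% 2L
  sf3 <- grepl("^(Walker|MotifC)", names(patterns))
  score <- 0L
  for (i in seq_along(patterns)) {
    sub <- if (!zones) protein else if (sf3[i])
      substr(protein, half + 1L, n) else substr(protein, 1L, half)
    if (regexpr(patterns[i], sub, perl = TRUE) > 0L) score <- score + 1L
  }
  score
}

#' Arginine-rich score of a Cp amino terminus
#'
#' Fraction of arginine plus lysine residues in the N-terminal window.
#'
#' @param protein amino-acid string.
#' @param window window size in residues (truncated if the protein is
#'   shorter; the truncated length is then the denominator).
#' @return fraction in [0, 1].
#' @export
arg_rich_score <- function(protein, window = 20L) {
  if (window < 1L) stop("window must be >= 1")
  w <- min(window, nchar(protein))
  if (w == 0L) return(0)
  head <- strsplit(substr(protein, 1L, w), "", fixed = TRUE)[[1]]
  sum(head %in% c("R", "K")) / w
}
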