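# End-to-end annotation pipeline and report writers.

#' Configuration for the annotation pipeline
#'
#' @param tables translation tables to try, in order; the annotator reports
#'   the lowest-numbered table yielding a motif-complete Rep.
#' @param start_codons allowed initiation codons (preference policy: 5'-most
#'   ATG, else the 5'-most alternative).
#' @param consensus nonanucleotide consensus; \code{N} matches any base.
#' @param max_mismatch mismatches tolerated against the consensus.
#' @param min_arm,max_loop,max_arm_mismatch stem-loop search parameters.
#' @param min_aa minimum Rep/Cp candidate length (aa).
#' @param min_aa_other minimum length for additional "other" ORFs.
#' @param max_intron maximum intron length (nt) for the spliced-Rep search.
#' @param rep_patterns Rep motif patterns.
#' @param arg_window Cp N-terminal window (aa).
#' @param species_threshold,genus_threshold ICTV demarcation thresholds (%).
#' @param identity_mode gap policy for identities.
#' @return list of class \code{scan_config}.
#' @export
scan_config <- function(tables = c(1L, 4L, 5L),
                        start_codons = default_start_codons(),
                        consensus = "NAGTATTAC", max_mismatch = 1L,
                        min_arm = 5L, max_loop = 13L, max_arm_mismatch = 1L,
                        min_aa = 100L, min_aa_other = 50L, max_intron = 200L,
                        rep_patterns = default_rep_motif_patterns(),
                        arg_window = 20L, species_threshold = 80,
                        genus_threshold = 55, identity_mode = "sdt") {
  stopifnot(all(tables %in% c(1L, 4L, 5L)),
            species_threshold > 0, species_threshold <= 100,
            genus_threshold > 0, genus_threshold <= 100)
  structure(as.list(environment()), class = "scan_config")
}

#' Annotate a circular CRESS DNA virus genome
#'
#' Runs the full characterization: locate the nonanucleotide motif and its
#' stem-loop, rotate to the position-one convention, enumerate ORFs under
#' each configured translation table (with the splice-aware Rep search),
#' stop at the lowest-numbered table giving a motif-complete Rep, assign
#' Rep/Cp roles and intergenic regions, score motifs and the arginine-rich
#' Cp terminus, and classify at genus level.
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param config a \code{\link{scan_config}}.
#' @param refs optional named reference genome sequences for the genus
#'   identity criterion.
#' @return object of class \code{genome_annotation}: fields \code{genome}
#'   (rotated), \code{ori}, \code{rep}, \code{cp}, \code{ir5}, \code{ir3},
#'   \code{other_orfs}, \code{table_id}, \code{table_alternatives},
#'   \code{genus}, \code{warnings}.
#' @export
annotate_genome <- function(genome, config = scan_config(), refs = NULL) {
  stopifnot(inherits(genome, "circular_genome"))
  warnings <- character()
  oriented <- tryCatch(
    orient_and_rotate(genome, config$consensus, config$max_mismatch,
                      config$min_arm, config$max_loop,
                      config$max_arm_mismatch),
    error = function(e) NULL)
  if (is.null(oriented)) {
    ann <- structure(list(genome = genome, ori = NULL, rep = NULL, cp = NULL,
                          ir5 = NULL, ir3 = NULL, other_orfs = NULL,
                          table_id = NA_integer_, table_alternatives = list(),
                          sense_rep_score = NA_real_,
                          n_motifs_expected = length(config$rep_patterns),
                          warnings = "no nonanucleotide motif found"),
                     class = "genome_annotation")
    ann$genus <- classify_genus(ann, refs, config$genus_threshold)
    return(ann)
  }
  g <- oriented$genome
  n_expected <- length(config$rep_patterns)

  per_table <- list()
  chosen <- NULL
  for (tb in config$tables) {
    orfs <- enumerate_orfs(g, tb, config$start_codons, config$min_aa_other,
                           exclude_start_in = c(1L, 9L))
    big <- orfs[orfs$aa_len >= config$min_aa, , drop = FALSE]
    spliced <- find_spliced_rep(g, tb, config$start_codons, config$min_aa,
                                config$max_intron, config$rep_patterns)
    roles <- assign_roles(big, spliced, g, config$rep_patterns,
                          config$arg_window)
    score <- if (is.null(roles$rep)) -1 else roles$rep$motif_score
    per_table[[as.character(tb)]] <- list(table_id = tb, roles = roles,
                                          orfs = orfs, score = score)
    if (score == n_expected) { chosen <- per_table[[as.character(tb)]]; break }
  }
  if (is.null(chosen)) {
    scores <- vapply(per_table, function(x) x$score, numeric(1))
    lens <- vapply(per_table, function(x)
      if (is.null(x$roles$rep)) 0 else x$roles$rep$aa_len, numeric(1))
    chosen <- per_table[[order(-scores, -lens)[1]]]
    warnings <- c(warnings, "no translation table gave a motif-complete Rep")
  }
  roles <- chosen$roles
  if (!roles$complete) {
    warnings <- c(warnings, "annotation incomplete: missing Rep or Cp ORF")
  }
  orfs <- chosen$orfs
  # highest Rep-motif score among sense ORFs (genus organization evidence)
  sense_big <- orfs[orfs$strand == "sense" & orfs$aa_len >= config$min_aa, ,
                    drop = FALSE]
  sense_rep_score <- if (nrow(sense_big) == 0L) -1 else
    max(vapply(sense_big$protein, function(p)
      rep_motif_score(p, config$rep_patterns), integer(1)))
  # remaining ORFs reported as "other"
  used <- character()
  if (!is.null(roles$rep)) used <- c(used, key_of(roles$rep))
  if (!is.null(roles$cp)) used <- c(used, key_of(roles$cp))
  other <- orfs[!(paste(orfs$strand, orfs$start_nt, orfs$end_nt) %in% used), ,
                drop = FALSE]

  ann <- structure(list(
    genome = g, ori = oriented$ori,
    rep = roles$rep, cp = roles$cp, ir5 = roles$ir5, ir3 = roles$ir3,
    other_orfs = other, table_id = chosen$table_id,
    table_alternatives = lapply(per_table, function(x)
      list(table_id = x$table_id, motif_score = x$score)),
    sense_rep_score = sense_rep_score,
    n_motifs_expected = n_expected,
    warnings = warnings), class = "genome_annotation")
  if (!is.null(ann$rep)) {
    ann$rep$motif_profile <- scan_rep_motifs(ann$rep$protein,
                                             config$rep_patterns)
  }
  ann$genus <- classify_genus(ann, refs, config$genus_threshold)
  ann
}

key_of <- function(o) paste(o$strand, o$start_nt, o$end_nt)

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d nt\n", x$genome$id,
              nchar(x$genome$seq)))
  if (is.null(x$ori)) {
    cat("  no ori found; genome unclassified\n")
    return(invisible(x))
  }
  cat(sprintf("  ori: motif %s at nt 1-9 (%d mismatch%s vs consensus)%s\n",
              x$ori$nona$motif_seq, x$ori$nona$mismatches,
              if (x$ori$nona$mismatches == 1L) "" else "es",
              if (is.null(x$ori$stem_loop)) "" else
                sprintf("; stem arms %d nt, loop %d nt",
                        x$ori$stem_loop$arm_len, x$ori$stem_loop$loop_len)))
  if (!is.null(x$rep)) {
    spl <- !is.null(x$rep$intron)
    cat(sprintf("  Rep: %d aa, table %d, start %s, nt %d-%d%s, motifs %d/%d\n",
                x$rep$aa_len, x$rep$table_id, x$rep$init_codon,
                x$rep$start_nt, x$rep$end_nt,
                if (spl) sprintf(" (intron nt %d-%d)", x$rep$intron[1],
                                 x$rep$intron[2]) else "",
                x$rep$motif_score, x$n_motifs_expected))
  }
  if (!is.null(x$cp)) {
    cat(sprintf("  Cp: %d aa, start %s, nt %d-%d, arg-rich score %.2f\n",
                x$cp$aa_len, x$cp$init_codon, x$cp$start_nt, x$cp$end_nt,
                x$cp$arg_score))
  }
  cat(sprintf("  5'-IR: nt %s; 3'-IR: %s\n",
              if (is.null(x$ir5)) "absent" else
                paste(x$ir5, collapse = "-"),
              if (is.null(x$ir3)) "absent" else
                paste0("nt ", x$ir3[1], "-", x$ir3[2])))
  cat(sprintf("  genus call: %s\n", x$genus$call))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @export
summary.genome_annotation <- function(object, ...) print(object, ...)

#' Write an annotation as GFF3
#'
#' Emits origin_of_replication (with motif and stem-arm subfeatures), CDS
#' features for Rep (multi-segment when spliced) and Cp, and intergenic
#' regions, in 1-based inclusive coordinates on the rotated genome.
#'
#' @param ann a \code{genome_annotation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_gff3 <- function(ann, path) {
  sid <- ann$genome$id
  L <- nchar(ann$genome$seq)
  rows <- list()
  add <- function(type, start, end, strand, id, parent = NULL, extra = "") {
    attrs <- paste0("ID=", id)
    if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
    if (nzchar(extra)) attrs <- paste0(attrs, ";", extra)
    rows[[length(rows) + 1L]] <<- sprintf(
      "%s\tcycloscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
      sid, type, start, end, strand, attrs)
  }
  if (!is.null(ann$ori)) {
    sl <- ann$ori$stem_loop
    add("origin_of_replication", 1L, 9L, "+", "ori",
        extra = paste0("motif=", ann$ori$nona$motif_seq))
    add("nonanucleotide_motif", 1L, 9L, "+", "ori.motif", "ori")
    if (!is.null(sl)) {
      add("stem_arm", sl$arm5[1], sl$arm5[2], "+", "ori.arm5", "ori")
      add("stem_arm", sl$arm3[1], sl$arm3[2], "+", "ori.arm3", "ori")
    }
  }
  emit_cds <- function(o, name) {
    if (is.null(o)) return()
    strand <- if (o$strand == "sense") "+" else "-"
    for (k in seq_along(o$segments)) {
      seg <- o$segments[[k]]
      lohi <- sort(c(((seg[1] - 1L) %% L) + 1L, ((seg[2] - 1L) %% L) + 1L))
      add("CDS", lohi[1], lohi[2], strand, paste0(name, ".cds"),
          extra = sprintf("gene=%s;transl_table=%d;segment=%d;product_aa=%d",
                          name, o$table_id, k, o$aa_len))
    }
  }
  emit_cds(ann$rep, "rep")
  emit_cds(ann$cp, "cp")
  if (!is.null(ann$ir3)) add("intergenic_region", ann$ir3[1], ann$ir3[2],
                             "+", "ir3")
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", sid, L),
               unlist(rows)), path)
  invisible(path)
}

#' Write an annotation as JSON
#'
#' @param ann a \code{genome_annotation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_json <- function(ann, path) {
  orf_json <- function(o) {
    if (is.null(o)) return(NULL)
    list(role = o$role, strand = o$strand, start_nt = o$start_nt,
         end_nt = o$end_nt, segments = o$segments, intron = o$intron,
         table_id = o$table_id, init_codon = o$init_codon,
         aa_len = o$aa_len, protein = o$protein,
         motif_score = o$motif_score, arg_score = o$arg_score)
  }
  x <- list(
    id = ann$genome$id,
    length_nt = nchar(ann$genome$seq),
    ori = if (is.null(ann$ori)) NULL else list(
      motif = ann$ori$nona$motif_seq,
      mismatches = ann$ori$nona$mismatches,
      stem_loop = if (is.null(ann$ori$stem_loop)) NULL else
        unclass(ann$ori$stem_loop),
      rotated = ann$ori$rotated),
    rep = orf_json(ann$rep), cp = orf_json(ann$cp),
    ir5 = ann$ir5, ir3 = ann$ir3,
    table_id = ann$table_id,
    genus = list(call = ann$genus$call,
                 evidence = as.list(ann$genus$evidence)),
    warnings = ann$warnings)
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a species assignment as two-column TSV
#'
#' @param sp a \code{species_assignment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_species_tsv <- function(sp, path) {
  utils::write.table(
    data.frame(label = names(sp$clusters), species = sp$clusters),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
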