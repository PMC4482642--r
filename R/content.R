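#' Per-genome content summary (footprint accounting)
#'
#' Tallies exonic, intronic, intergenic and repeat base counts for one
#' annotated genome, in either of two accounting modes. `summed` adds
#' per-transcript exon and intron lengths, so alternatively spliced bases
#' count once per transcript and the totals can exceed the genome size —
#' this matches how published per-species content tables are assembled.
#' `union` de-duplicates over the genome: exonic bases are the union of all
#' exons, intronic bases are intron-covered bases not in any exon, and the
#' unspliced transcript footprint is the union of transcript spans.
#' Intergenic DNA is always the complement of the union of gene spans.
#' Repeat bases overlapping the exonic union are "coding" (with gene-span
#' overlap as an alternative definition), the remainder "noncoding".
#'
#' @param annotation a `genome_annotation`.
#' @param mode "summed" (default) or "union".
#' @param repeat_coding_by overlap target defining coding repeats:
#'   "exon" (default) or "gene_span".
#' @return object of class `content_summary`: list with exonic_bp,
#'   intronic_bp, intergenic_bp, total_bp, repeat_coding_bp,
#'   repeat_noncoding_bp, repeat_total_bp, gene_count,
#'   transcript_footprint_bp and mode.
#' @export
summarize_content <- function(annotation, mode = c("summed", "union"),
                              repeat_coding_by = c("exon", "gene_span")) {
  mode <- match.arg(mode)
  repeat_coding_by <- match.arg(repeat_coding_by)
  ann <- annotation
  ex <- ann$exons
  tx <- ann$transcripts
  exon_iv <- if (nrow(ex)) interval_set(ex$seqid, ex$start, ex$end) else interval_set()
  # per-transcript introns
  intron_iv <- interval_set()
  if (nrow(ex)) {
    o <- order(ex$tx_id, ex$start)
    exo <- ex[o, ]
    same <- c(FALSE, exo$tx_id[-1] == exo$tx_id[-nrow(exo)])
    istart <- exo$end[-nrow(exo)][same[-1]]
    iend <- exo$start[-1][same[-1]]
    isq <- exo$seqid[-1][same[-1]]
    keep <- iend > istart
    if (any(keep)) intron_iv <- interval_set(isq[keep], istart[keep], iend[keep])
  }
  tx_iv <- if (nrow(tx)) interval_set(tx$seqid, tx$start, tx$end) else interval_set()
  gene_iv <- gene_spans(ann)
  total_bp <- sum(ann$seq_lengths)
  intergenic_bp <- total_bp - iv_total(iv_union(gene_iv))

  if (mode == "summed") {
    exonic <- iv_total(exon_iv)
    intronic <- iv_total(intron_iv)
    footprint <- iv_total(tx_iv)
  } else {
    ex_u <- iv_union(exon_iv)
    exonic <- iv_total(ex_u)
    intronic <- iv_total(iv_setdiff(intron_iv, ex_u))
    footprint <- iv_total(iv_union(tx_iv))
  }
  rep_u <- iv_union(ann$repeats)
  repeat_total <- iv_total(rep_u)
  coding_target <- if (repeat_coding_by == "exon") iv_union(exon_iv) else iv_union(gene_iv)
  repeat_coding <- iv_total(iv_intersect(rep_u, coding_target))
  structure(list(
    exonic_bp = exonic, intronic_bp = intronic, intergenic_bp = intergenic_bp,
    total_bp = total_bp,
    repeat_coding_bp = repeat_coding,
    repeat_noncoding_bp = repeat_total - repeat_coding,
    repeat_total_bp = repeat_total,
    gene_count = nrow(ann$genes),
    transcript_footprint_bp = footprint,
    mode = mode), class = "content_summary")
}

#' @export
print.content_summary <- function(x, ...) {
  mb <- function(v) sprintf("%.2f Mb", v / 1e6)
  cat("Genome content (", x$mode, " mode)\n", sep = "")
  cat("  exons:", mb(x$exonic_bp), " introns:", mb(x$intronic_bp),
      " intergenic:", mb(x$intergenic_bp), " total:", mb(x$total_bp), "\n")
  cat("  repeats:", mb(x$repeat_total_bp),
      sprintf("(coding %s, noncoding %s)\n",
              mb(x$repeat_coding_bp), mb(x$repeat_noncoding_bp)))
  cat("  genes:", x$gene_count,
      " unspliced transcript footprint:", mb(x$transcript_footprint_bp), "\n")
  invisible(x)
}

#' Percent reduction of a genome relative to a reference size
#'
#' `100 * (reference - size) / reference`; e.g. a 100 Mb selfer against the
#' 130 Mb outcrossing average is a 23% reduction.
#'
#' @param size_bp genome size (any unit, same as reference).
#' @param reference_bp reference size (> 0).
#' @param digits optional rounding of the reported percent.
#' @return percent reduction (negative for genomes larger than reference).
#' @export
percent_reduction <- function(size_bp, reference_bp, digits = NULL) {
  if (any(reference_bp <= 0)) stop("reference size must be > 0")
  out <- 100 * (reference_bp - size_bp) / reference_bp
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Footprint fractions of assembled and estimated genome size
#'
#' Expresses an unspliced transcript footprint as a percent of the
#' assembled and of the independently estimated genome size, and as a
#' percent difference against other species' footprints.
#'
#' @param footprint_bp focal species footprint.
#' @param assembled_bp assembled genome size (> 0).
#' @param estimated_bp estimated (e.g. flow-cytometry) genome size (> 0).
#' @param other_footprints named numeric of comparator species' footprints.
#' @return list: pct_of_assembled, pct_of_estimated, pct_vs (named percent
#'   differences, positive when the focal footprint is larger).
#' @export
footprint_fractions <- function(footprint_bp, assembled_bp, estimated_bp,
                                other_footprints = numeric()) {
  stopifnot(footprint_bp > 0, assembled_bp > 0, estimated_bp > 0)
  pct_vs <- if (length(other_footprints))
    100 * (footprint_bp - other_footprints) / other_footprints
  else stats::setNames(numeric(), character())
  list(pct_of_assembled = 100 * footprint_bp / assembled_bp,
       pct_of_estimated = 100 * footprint_bp / estimated_bp,
       pct_vs = pct_vs)
}
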