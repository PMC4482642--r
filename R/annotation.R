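#' Genome annotation container
#'
#' Holds one species' gene models, repeats and chromosome-class labels in
#' 0-based half-open coordinates. The package-wide invariants are enforced
#' at construction: every exon lies within its transcript span, every
#' transcript within its gene span, every gene within its scaffold, and the
#' exon list of one transcript is non-overlapping.
#'
#' @param seq_lengths named numeric vector: seqid -> scaffold length (bp).
#' @param genes data.frame with columns gene_id, seqid, start, end, strand.
#' @param transcripts data.frame with columns tx_id, gene_id, seqid, start,
#'   end, strand.
#' @param exons,cds,utr5,utr3 data.frames with columns tx_id, seqid, start,
#'   end (cds/utr tables may be empty).
#' @param repeats interval set of repeat annotations (may carry a `family`
#'   column).
#' @param chrom_class named character vector seqid -> one of
#'   "autosome", "X", "unassigned". Missing seqids default to "unassigned".
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(seq_lengths, genes, transcripts, exons,
                              cds = NULL, utr5 = NULL, utr3 = NULL,
                              repeats = NULL, chrom_class = NULL) {
  empty_tx_tab <- function(x) {
    if (is.null(x) || nrow(as.data.frame(x)) == 0)
      data.frame(tx_id = character(), seqid = character(),
                 start = numeric(), end = numeric())
    else as.data.frame(x)
  }
  cds <- empty_tx_tab(cds); utr5 <- empty_tx_tab(utr5); utr3 <- empty_tx_tab(utr3)
  if (is.null(repeats)) repeats <- interval_set()
  cc <- rep("unassigned", length(seq_lengths))
  names(cc) <- names(seq_lengths)
  if (!is.null(chrom_class)) {
    bad <- setdiff(chrom_class, c("autosome", "X", "unassigned"))
    if (length(bad)) stop("unknown chromosome class: ", paste(bad, collapse = ", "))
    cc[names(chrom_class)] <- chrom_class
  }
  ann <- structure(list(
    seq_lengths = seq_lengths,
    genes = as.data.frame(genes),
    transcripts = as.data.frame(transcripts),
    exons = as.data.frame(exons),
    cds = cds, utr5 = utr5, utr3 = utr3,
    repeats = as_interval_set(repeats),
    chrom_class = cc
  ), class = "genome_annotation")
  validate_annotation(ann)
  ann
}

#' Validate a genome annotation
#'
#' @param ann a `genome_annotation`.
#' @return `ann`, invisibly; stops with a consistency error otherwise.
#' @export
validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  g <- ann$genes; tx <- ann$transcripts; ex <- ann$exons
  if (anyDuplicated(g$gene_id)) stop("duplicate gene ids")
  if (anyDuplicated(tx$tx_id)) stop("duplicate transcript ids")
  if (nrow(g)) {
    if (!all(g$seqid %in% names(ann$seq_lengths)))
      stop("gene on unknown scaffold")
    if (any(g$start < 0) || any(g$end > ann$seq_lengths[g$seqid]))
      stop("gene span outside scaffold bounds")
  }
  if (nrow(tx)) {
    m <- match(tx$gene_id, g$gene_id)
    if (anyNA(m)) stop("transcript references unknown gene: ",
                       tx$tx_id[which(is.na(m))[1]])
    if (any(tx$start < g$start[m]) || any(tx$end > g$end[m]))
      stop("transcript span outside its gene span")
  }
  check_children <- function(tab, what) {
    if (!nrow(tab)) return(invisible())
    m <- match(tab$tx_id, tx$tx_id)
    if (anyNA(m)) stop(what, " references unknown transcript: ",
                       tab$tx_id[which(is.na(m))[1]])
    if (any(tab$start < tx$start[m]) || any(tab$end > tx$end[m]))
      stop(what, " outside its transcript span")
  }
  check_children(ex, "exon")
  check_children(ann$cds, "CDS")
  check_children(ann$utr5, "5' UTR")
  check_children(ann$utr3, "3' UTR")
  if (nrow(ex)) {
    o <- order(ex$tx_id, ex$start)
    exo <- ex[o, ]
    same <- exo$tx_id[-1] == exo$tx_id[-nrow(exo)]
    if (any(same & exo$start[-1] < exo$end[-nrow(exo)]))
      stop("overlapping exons within one transcript")
  }
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:",
      length(x$seq_lengths), "scaffolds (",
      format(sum(x$seq_lengths), big.mark = ","), "bp ),",
      nrow(x$genes), "genes,", nrow(x$transcripts), "transcripts,",
      nrow(x$repeats), "repeat intervals\n")
  cc <- table(x$chrom_class[unique(x$genes$seqid)])
  if (length(cc)) cat("  gene-bearing scaffold classes:",
                      paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Canonical transcript per gene
#'
#' The canonical transcript is the one with the largest summed exon length;
#' ties break by lexicographically smallest transcript id.
#'
#' @param ann a `genome_annotation`.
#' @return data.frame gene_id, tx_id.
#' @export
canonical_transcripts <- function(ann) {
  tx <- ann$transcripts
  if (!nrow(tx)) return(data.frame(gene_id = character(), tx_id = character()))
  ex <- ann$exons
  exlen <- tapply(ex$end - ex$start, ex$tx_id, sum)
  tx$exlen <- as.numeric(exlen[tx$tx_id])
  tx$exlen[is.na(tx$exlen)] <- 0
  tx <- tx[order(tx$gene_id, -tx$exlen, tx$tx_id), ]
  tx <- tx[!duplicated(tx$gene_id), ]
  data.frame(gene_id = tx$gene_id, tx_id = tx$tx_id, stringsAsFactors = FALSE)
}

#' Gene spans of an annotation as an interval set
#' @param ann a `genome_annotation`.
#' @param classes optional chromosome classes to keep (e.g. "X").
#' @return `interval_set` of (non-unioned) gene spans.
#' @export
gene_spans <- function(ann, classes = NULL) {
  g <- ann$genes
  if (!is.null(classes)) g <- g[ann$chrom_class[g$seqid] %in% classes, , drop = FALSE]
  if (!nrow(g)) return(interval_set())
  interval_set(g$seqid, g$start, g$end)
}
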