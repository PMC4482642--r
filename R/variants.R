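#' Partition a genome into mutually exclusive feature classes
#'
#' Every base is assigned exactly one class by the precedence
#' CDS_exon > UTR5 > UTR3 > intron > TSS > TE > intergenic (configurable).
#' The TSS class is a fixed window immediately upstream of each transcript
#' start, strand-aware and clipped to the scaffold.
#'
#' @param annotation a `genome_annotation`.
#' @param tss_window_bp upstream window defining the TSS class (bp).
#' @param precedence character vector ordering the non-intergenic classes;
#'   earlier wins.
#' @return list with `class_map` (named list of normalized interval sets,
#'   a partition of the genome), `totals` (bases per class) and the
#'   precedence used.
#' @export
classify_sites <- function(annotation, tss_window_bp = 200,
                           precedence = c("CDS_exon", "UTR5", "UTR3",
                                          "intron", "TSS", "TE")) {
  ann <- annotation
  tx <- ann$transcripts
  ex <- ann$exons
  introns <- NULL
  if (nrow(ex)) {
    o <- order(ex$tx_id, ex$start)
    exo <- ex[o, ]
    same <- c(FALSE, exo$tx_id[-1] == exo$tx_id[-nrow(exo)])
    istart <- exo$end[-nrow(exo)][same[-1]]
    iend <- exo$start[-1][same[-1]]
    isq <- exo$seqid[-1][same[-1]]
    keep <- iend > istart
    if (any(keep)) introns <- interval_set(isq[keep], istart[keep], iend[keep])
  }
  tss <- NULL
  if (nrow(tx) && tss_window_bp > 0) {
    plus <- tx$strand != "-"
    s <- ifelse(plus, tx$start - tss_window_bp, tx$end)
    e <- ifelse(plus, tx$start, tx$end + tss_window_bp)
    s <- pmax(0, s)
    e <- pmin(ann$seq_lengths[tx$seqid], e)
    keep <- e > s
    if (any(keep)) tss <- interval_set(tx$seqid[keep], s[keep], e[keep])
  }
  raw <- list(
    CDS_exon = if (nrow(ann$cds)) interval_set(ann$cds$seqid, ann$cds$start, ann$cds$end) else interval_set(),
    UTR5 = if (nrow(ann$utr5)) interval_set(ann$utr5$seqid, ann$utr5$start, ann$utr5$end) else interval_set(),
    UTR3 = if (nrow(ann$utr3)) interval_set(ann$utr3$seqid, ann$utr3$start, ann$utr3$end) else interval_set(),
    intron = if (is.null(introns)) interval_set() else introns,
    TSS = if (is.null(tss)) interval_set() else tss,
    TE = if (nrow(ann$repeats)) as_interval_set(ann$repeats) else interval_set())
  if (length(setdiff(precedence, names(raw))))
    stop("unknown class in precedence: ",
         paste(setdiff(precedence, names(raw)), collapse = ", "))
  class_map <- list()
  taken <- interval_set()
  for (cl in precedence) {
    iv <- iv_setdiff(raw[[cl]], taken)
    class_map[[cl]] <- iv
    taken <- iv_union(rbind(as.data.frame(taken)[c("seqid", "start", "end")],
                            as.data.frame(iv)[c("seqid", "start", "end")]))
  }
  class_map$intergenic <- iv_complement(taken, ann$seq_lengths)
  totals <- vapply(class_map, iv_total, 0)
  list(class_map = class_map, totals = totals, precedence = precedence,
       seq_lengths = ann$seq_lengths)
}

#' Look up the feature class of genomic positions
#' @param cmap result of [classify_sites()].
#' @param seqid,pos vectors of positions (0-based).
#' @return character vector of classes; `NA` for positions on scaffolds
#'   absent from the map.
#' @export
lookup_class <- function(cmap, seqid, pos) {
  all_iv <- do.call(rbind, lapply(names(cmap$class_map), function(cl) {
    iv <- cmap$class_map[[cl]]
    if (nrow(iv) == 0) return(NULL)
    data.frame(seqid = iv$seqid, start = iv$start, end = iv$end, class = cl,
               stringsAsFactors = FALSE)
  }))
  out <- rep(NA_character_, length(pos))
  for (sq in unique(seqid)) {
    ivs <- all_iv[all_iv$seqid == sq, , drop = FALSE]
    sel <- which(seqid == sq)
    if (nrow(ivs) == 0) next
    ivs <- ivs[order(ivs$start), ]
    idx <- findInterval(pos[sel], ivs$start)
    hit <- idx > 0 & pos[sel] < ivs$end[pmax(idx, 1)]
    out[sel[hit]] <- ivs$class[idx[hit]]
  }
  out
}

#' Residual polymorphism partitioned by feature class
#'
#' Counts assayed and polymorphic sites per feature class after the site
#' filters used for inbred-genome quality control: sites with per-base depth
#' above `max_depth` (poorly assembled, collapsed repeats) or quality below
#' `min_quality` (Q10 Phred+33 = 90% certainty) are excluded from both the
#' numerator and denominator. Sites without depth are likewise excluded
#' (flagged by the reader) and counted.
#'
#' @param sites data.frame from [read_vcf_sites()].
#' @param cmap class map from [classify_sites()].
#' @param max_depth maximum per-site depth (default 600).
#' @param min_quality minimum site quality (default Q10).
#' @param genic_classes classes pooled into the headline genic estimate.
#' @return object of class `site_class_tally`: data.frame (class,
#'   assayed_sites, polymorphic_sites, fraction, percent) with attributes
#'   `genic_percent`, `n_filtered`, `n_unmapped`.
#' @export
polymorphism_by_class <- function(sites, cmap, max_depth = 600,
                                  min_quality = 10,
                                  genic_classes = c("CDS_exon", "UTR5",
                                                    "UTR3", "intron")) {
  usable <- !sites$dp_missing & !is.na(sites$depth) &
    sites$depth <= max_depth &
    !is.na(sites$base_quality) & sites$base_quality >= min_quality
  n_filtered <- sum(!usable)
  kept <- sites[usable, , drop = FALSE]
  cls <- if ("class" %in% names(kept) && !anyNA(kept$class)) kept$class
         else lookup_class(cmap, kept$seqid, kept$pos)
  unmapped <- is.na(cls)
  n_unmapped <- sum(unmapped)
  kept <- kept[!unmapped, , drop = FALSE]
  cls <- cls[!unmapped]
  classes <- names(cmap$class_map)
  assayed <- vapply(classes, function(cl) sum(cls == cl), 0)
  poly <- vapply(classes, function(cl) sum(kept$is_variant[cls == cl]), 0)
  tal <- data.frame(class = classes, assayed_sites = assayed,
                    polymorphic_sites = poly,
                    fraction = ifelse(assayed > 0, poly / assayed, NA),
                    stringsAsFactors = FALSE)
  tal$percent <- 100 * tal$fraction
  gi <- tal$class %in% genic_classes
  genic_assayed <- sum(tal$assayed_sites[gi])
  genic_poly <- sum(tal$polymorphic_sites[gi])
  structure(tal, class = c("site_class_tally", "data.frame"),
            genic_percent = if (genic_assayed > 0) 100 * genic_poly / genic_assayed else NA,
            genic_assayed = genic_assayed,
            genic_polymorphic = genic_poly,
            n_filtered = n_filtered, n_unmapped = n_unmapped)
}

#' @export
print.site_class_tally <- function(x, ...) {
  cat("Residual polymorphism by feature class",
      sprintf("(%d sites filtered, %d unmapped)\n",
              attr(x, "n_filtered"), attr(x, "n_unmapped")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("genic (exon+UTR+intron) polymorphism: %.4g%% of %s sites\n",
              attr(x, "genic_percent"),
              format(attr(x, "genic_assayed"), big.mark = ",")))
  invisible(x)
}

#' Segregation-distortion and representation QC for RIL markers
#'
#' Applies, in order: (1) markers with parental-A frequency above `freq_hi`
#' or below `freq_lo` (computed over non-missing, non-heterozygous calls)
#' are flagged, and every marker on a scaffold with more than
#' `max_flagged_per_scaffold` flagged markers is dropped; (2) markers
#' genotyped in fewer than `min_lines` lines (or with no informative call at
#' all) are dropped as low representation; (3) markers with an identical
#' genotype pattern are collapsed to one representative, the duplicates
#' recorded for later re-addition.
#'
#' @param genotypes marker x line character matrix (A/B/H/-).
#' @param scaffold_map named character: marker id -> scaffold.
#' @param freq_hi,freq_lo distortion flag thresholds (defaults 0.80 / 0.20).
#' @param max_flagged_per_scaffold scaffolds with more flagged markers than
#'   this lose all their markers (default 5).
#' @param min_lines minimum lines genotyped (default 40).
#' @return object of class `marker_qc_report`: list with counts, retained
#'   marker ids, flagged scaffolds and the duplicate map.
#' @export
marker_qc <- function(genotypes, scaffold_map, freq_hi = 0.80, freq_lo = 0.20,
                      max_flagged_per_scaffold = 5, min_lines = 40) {
  stopifnot(is.matrix(genotypes), !is.null(rownames(genotypes)))
  markers <- rownames(genotypes)
  if (!all(markers %in% names(scaffold_map)))
    stop("scaffold_map missing markers: ",
         paste(utils::head(setdiff(markers, names(scaffold_map))), collapse = ", "))
  n_a <- rowSums(genotypes == "A")
  n_b <- rowSums(genotypes == "B")
  informative <- n_a + n_b
  freq_a <- ifelse(informative > 0, n_a / informative, NA)
  flagged <- !is.na(freq_a) & (freq_a > freq_hi | freq_a < freq_lo)
  sc <- scaffold_map[markers]
  flagged_per_scaffold <- tapply(flagged, sc, sum)
  bad_scaffolds <- names(flagged_per_scaffold)[
    flagged_per_scaffold > max_flagged_per_scaffold]
  drop_distort <- sc %in% bad_scaffolds
  present <- rowSums(genotypes != "-")
  drop_lowrep <- !drop_distort & (present < min_lines | informative == 0)
  keep <- !drop_distort & !drop_lowrep
  pattern <- apply(genotypes[keep, , drop = FALSE], 1, paste, collapse = "")
  first <- !duplicated(pattern)
  kept_ids <- markers[keep]
  retained <- kept_ids[first]
  dup_map <- split(kept_ids[!first],
                   retained[match(pattern[!first], pattern[first])])
  structure(list(
    input_markers = length(markers),
    dropped_by_scaffold_distortion = sum(drop_distort),
    dropped_low_representation = sum(drop_lowrep),
    dropped_duplicate_only = sum(!first),
    retained_markers = length(retained),
    retained = retained,
    flagged_scaffolds = bad_scaffolds,
    flagged_markers = markers[flagged],
    duplicates = dup_map
  ), class = "marker_qc_report")
}

#' @export
print.marker_qc_report <- function(x, ...) {
  cat("Marker QC:", x$input_markers, "in ->", x$retained_markers, "retained\n")
  cat("  dropped on distorted scaffolds:", x$dropped_by_scaffold_distortion,
      "( scaffolds:", paste(x$flagged_scaffolds, collapse = ", "), ")\n")
  cat("  dropped low representation:", x$dropped_low_representation, "\n")
  cat("  collapsed duplicates:", x$dropped_duplicate_only, "\n")
  invisible(x)
}
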