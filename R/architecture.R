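#' Intergenic gap lengths
#'
#' Per scaffold, overlapping gene spans are unioned first, then the gaps
#' between consecutive spans are measured. Scaffold-end flanks are not
#' intergenic spaces; zero-length (book-ended) gaps cannot occur after the
#' union and negative gaps are impossible.
#'
#' @param annotation a `genome_annotation`.
#' @param class_filter optional chromosome classes to keep
#'   (e.g. "X", or c("autosome")).
#' @return numeric vector of gap lengths (bp).
#' @export
intergenic_spaces <- function(annotation, class_filter = NULL) {
  g <- iv_union(gene_spans(annotation, classes = class_filter))
  if (nrow(g) < 2) return(numeric())
  gaps <- unlist(lapply(split(g, g$seqid), function(x) {
    if (nrow(x) < 2) return(numeric())
    x$start[-1] - x$end[-nrow(x)]
  }), use.names = FALSE)
  gaps[gaps > 0]
}

#' Per-gene size metrics from the canonical transcript
#'
#' One record per gene: summed exon length and summed intron length of the
#' canonical (largest summed-exon) transcript, the gene span, and the
#' protein length in amino acids (CDS length / 3 - 1, absent when the gene
#' has no CDS). For a single-transcript gene span = exon_sum + intron_sum.
#'
#' @param annotation a `genome_annotation`.
#' @param ortholog_filter optional set of gene ids to restrict to.
#' @param species optional species label copied into the output.
#' @return data.frame gene_id, species, chrom_class, exon_sum_bp,
#'   intron_sum_bp, span_bp, protein_aa.
#' @export
gene_metrics <- function(annotation, ortholog_filter = NULL, species = NA_character_) {
  ann <- annotation
  g <- ann$genes
  if (!is.null(ortholog_filter)) g <- g[g$gene_id %in% ortholog_filter, , drop = FALSE]
  canon <- canonical_transcripts(ann)
  canon <- canon[canon$gene_id %in% g$gene_id, , drop = FALSE]
  ex <- ann$exons[ann$exons$tx_id %in% canon$tx_id, , drop = FALSE]
  exon_sum <- tapply(ex$end - ex$start, ex$tx_id, sum)
  n_exon <- tapply(ex$tx_id, ex$tx_id, length)
  cds <- ann$cds[ann$cds$tx_id %in% canon$tx_id, , drop = FALSE]
  cds_sum <- tapply(cds$end - cds$start, cds$tx_id, sum)
  m <- match(g$gene_id, canon$gene_id)
  tx_id <- canon$tx_id[m]
  tx <- ann$transcripts
  tx_span <- stats::setNames(tx$end - tx$start, tx$tx_id)[tx_id]
  es <- as.numeric(exon_sum[tx_id]); es[is.na(es)] <- 0
  cl <- as.numeric(cds_sum[tx_id])
  data.frame(
    gene_id = g$gene_id,
    species = species,
    chrom_class = unname(ann$chrom_class[g$seqid]),
    exon_sum_bp = es,
    intron_sum_bp = as.numeric(tx_span) - es,
    exon_count = as.numeric(n_exon[tx_id]),
    span_bp = g$end - g$start,
    protein_aa = ifelse(is.na(cl), NA, cl / 3 - 1),
    stringsAsFactors = FALSE)
}

.new_test_result <- function(statistic, df, p_raw, method, groups,
                             p_adjusted = NA_real_, degenerate = FALSE) {
  structure(list(statistic = statistic, df = df, p_raw = p_raw,
                 p_adjusted = p_adjusted, method = method, groups = groups,
                 degenerate = degenerate),
            class = "arch_test")
}

#' @export
print.arch_test <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4g, df = %s, p = %.3g%s%s\n",
              x$method, paste(x$groups, collapse = " vs "),
              x$statistic, ifelse(is.na(x$df), "-", x$df), x$p_raw,
              if (!is.na(x$p_adjusted)) sprintf(" (adj %.3g)", x$p_adjusted) else "",
              if (isTRUE(x$degenerate)) " [degenerate: all values tied]" else ""))
  invisible(x)
}

#' Kruskal-Wallis rank sum test over a list of groups
#'
#' Tie-corrected H with df = k - 1 and a chi-square upper-tail p-value.
#' Degenerate input (every observation identical) is reported as H = 0,
#' p = 1 and flagged rather than propagating NaN.
#'
#' @param groups list of >= 2 numeric vectors (total n >= 3).
#' @return an `arch_test` (statistic, df, p_raw, method, groups).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  sizes <- lengths(groups)
  if (any(sizes < 1) || sum(sizes) < 3)
    stop("each group needs >= 1 observation and >= 3 in total")
  x <- unlist(groups, use.names = FALSE)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  if (length(unique(x)) == 1)
    return(.new_test_result(0, length(groups) - 1, 1,
                            "Kruskal-Wallis rank sum test", nm, degenerate = TRUE))
  grp <- factor(rep(nm, sizes), levels = nm)
  kt <- stats::kruskal.test(x, grp)
  .new_test_result(unname(kt$statistic), unname(kt$parameter),
                   kt$p.value, "Kruskal-Wallis rank sum test", nm)
}

#' Pairwise Wilcoxon rank sum tests with Bonferroni correction
#'
#' One two-sided rank-sum test per unordered pair of groups;
#' `p_adjusted = min(1, p * m)` with m the number of tested pairs. Exact
#' p-values for small untied samples, normal approximation with continuity
#' correction otherwise (the stats::wilcox.test default).
#'
#' @param groups named list of numeric vectors.
#' @param correction only "bonferroni" is offered.
#' @return data.frame group_a, group_b, statistic, p_raw, p_adjusted.
#' @export
pairwise_wilcoxon <- function(groups, correction = "bonferroni") {
  correction <- match.arg(correction)
  stopifnot(is.list(groups), length(groups) >= 2)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  empty <- lengths(groups) == 0
  if (any(empty)) {
    warning("empty group(s) skipped: ", paste(nm[empty], collapse = ", "))
    groups <- groups[!empty]; nm <- nm[!empty]
  }
  pairs <- utils::combn(seq_along(groups), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (length(unique(c(groups[[a]], groups[[b]]))) == 1) {
      w <- list(statistic = length(groups[[a]]) * length(groups[[b]]) / 2,
                p.value = 1)
    } else {
      w <- suppressWarnings(stats::wilcox.test(groups[[a]], groups[[b]]))
    }
    data.frame(group_a = nm[a], group_b = nm[b],
               statistic = unname(w$statistic), p_raw = w$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out
}

#' Full architecture comparison battery
#'
#' Runs, for each species, the within-species X-versus-autosome
#' Kruskal-Wallis tests on intergenic spaces, gene spans and protein sizes,
#' and, across species, per-chromosome-class Kruskal-Wallis tests followed
#' by Bonferroni-corrected pairwise Wilcoxon rank sum tests. Also returns a
#' per-species, per-class table of mean/median exon, intron, gene span and
#' intergenic space.
#'
#' @param annotations named list of `genome_annotation`s (name = species).
#' @param orthologs optional ortholog table ([read_orthologs()] format);
#'   when given, gene-level metrics are restricted to genes whose id occurs
#'   in every species (conserved co-orthologs).
#' @param alpha significance level recorded in the output (default 0.05).
#' @return list of class `architecture_report`: `summary` (Table-style
#'   means/medians), `within_species` and `between_species` test tables.
#' @export
compare_architecture <- function(annotations, orthologs = NULL, alpha = 0.05) {
  stopifnot(is.list(annotations), length(annotations) >= 1,
            !is.null(names(annotations)))
  filt <- NULL
  if (!is.null(orthologs)) {
    tab <- table(unique(orthologs[c("gene_id", "species")])$gene_id)
    filt <- names(tab)[tab == length(annotations)]
  }
  sp_names <- names(annotations)
  metrics <- lapply(sp_names, function(sp)
    gene_metrics(annotations[[sp]], ortholog_filter = filt, species = sp))
  names(metrics) <- sp_names
  gaps <- lapply(sp_names, function(sp) list(
    autosome = intergenic_spaces(annotations[[sp]], "autosome"),
    X = intergenic_spaces(annotations[[sp]], "X")))
  names(gaps) <- sp_names

  # summary table
  srows <- list()
  for (sp in sp_names) for (cl in c("autosome", "X")) {
    mm <- metrics[[sp]]
    mm <- mm[mm$chrom_class == cl, , drop = FALSE]
    gg <- gaps[[sp]][[cl]]
    srows[[paste(sp, cl)]] <- data.frame(
      species = sp, chrom_class = cl, n_genes = nrow(mm),
      mean_exon = mean(mm$exon_sum_bp), median_exon = stats::median(mm$exon_sum_bp),
      mean_intron = mean(mm$intron_sum_bp), median_intron = stats::median(mm$intron_sum_bp),
      mean_total = mean(mm$span_bp), median_total = stats::median(mm$span_bp),
      mean_intergenic = mean(gg), median_intergenic = stats::median(gg),
      n_intergenic = length(gg),
      mean_protein = mean(mm$protein_aa, na.rm = TRUE),
      median_protein = stats::median(mm$protein_aa, na.rm = TRUE))
  }
  summary_tab <- do.call(rbind, srows)
  rownames(summary_tab) <- NULL

  test_to_row <- function(t, species, measure, comparison) {
    data.frame(species = species, measure = measure, comparison = comparison,
               statistic = t$statistic, df = t$df, p_raw = t$p_raw,
               degenerate = t$degenerate, stringsAsFactors = FALSE)
  }
  within <- list()
  for (sp in sp_names) {
    mm <- metrics[[sp]]
    two <- function(v, cls) list(autosome = v[cls == "autosome"],
                                 X = v[cls == "X"])
    pa <- mm[!is.na(mm$protein_aa), , drop = FALSE]
    sets <- list(intergenic = gaps[[sp]],
                 gene_size = two(mm$span_bp, mm$chrom_class),
                 protein_size = two(pa$protein_aa, pa$chrom_class))
    for (ms in names(sets)) {
      gl <- sets[[ms]]
      if (any(lengths(gl) == 0) || sum(lengths(gl)) < 3) {
        message(sp, ": skipping X-vs-autosome ", ms, " (too little data)")
        next
      }
      within[[paste(sp, ms)]] <- test_to_row(kruskal_wallis(gl), sp, ms,
                                             "X_vs_autosome")
    }
  }
  within <- if (length(within)) do.call(rbind, within) else NULL
  if (!is.null(within)) rownames(within) <- NULL

  between_kw <- list(); between_pw <- list()
  if (length(sp_names) >= 2) {
    for (cl in c("autosome", "X")) {
      pull <- list(
        intergenic = lapply(gaps, `[[`, cl),
        gene_size = lapply(metrics, function(mm) mm$span_bp[mm$chrom_class == cl]),
        protein_size = lapply(metrics, function(mm)
          mm$protein_aa[mm$chrom_class == cl & !is.na(mm$protein_aa)]))
      for (ms in names(pull)) {
        gl <- pull[[ms]]
        if (any(lengths(gl) == 0) || sum(lengths(gl)) < 3) next
        kw <- kruskal_wallis(gl)
        between_kw[[paste(cl, ms)]] <- test_to_row(kw, "all", ms,
                                                   paste0("between_species_", cl))
        pw <- pairwise_wilcoxon(gl)
        pw$measure <- ms; pw$chrom_class <- cl
        between_pw[[paste(cl, ms)]] <- pw
      }
    }
  }
  structure(list(
    summary = summary_tab,
    within_species = within,
    between_species = if (length(between_kw)) do.call(rbind, between_kw) else NULL,
    pairwise = if (length(between_pw)) do.call(rbind, between_pw) else NULL,
    alpha = alpha,
    n_ortholog_filter = if (is.null(filt)) NA_integer_ else length(filt)
  ), class = "architecture_report")
}

#' @export
print.architecture_report <- function(x, ...) {
  cat("Architecture comparison across",
      length(unique(x$summary$species)), "species\n")
  if (!is.na(x$n_ortholog_filter))
    cat("  restricted to", x$n_ortholog_filter, "conserved co-orthologs\n")
  print(x$summary, digits = 4, row.names = FALSE)
  if (!is.null(x$within_species)) {
    cat("\nWithin-species X vs autosome (Kruskal-Wallis):\n")
    print(x$within_species, digits = 4, row.names = FALSE)
  }
  if (!is.null(x$between_species)) {
    cat("\nBetween-species per class (Kruskal-Wallis):\n")
    print(x$between_species, digits = 4, row.names = FALSE)
  }
  invisible(x)
}
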