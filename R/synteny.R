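#' Ortholog pairs between two species from a long ortholog table
#'
#' Rows of the long table sharing a `gene_id` form one ortholog group.
#' Groups represented in both requested species are reduced to 1:1 pairs
#' (if a group has several members in a species, the longest gene wins,
#' ties broken by lexicographic id).
#'
#' @param orthologs data.frame from [read_orthologs()].
#' @param species_a,species_b the two species to pair.
#' @return data.frame gene_a, seqid_a, start_a, end_a, gene_b, seqid_b,
#'   start_b, end_b (one row per ortholog pair).
#' @export
ortholog_pairs <- function(orthologs, species_a, species_b) {
  pick <- function(sp) {
    t <- orthologs[orthologs$species == sp, , drop = FALSE]
    t <- t[order(t$gene_id, -(t$end - t$start), t$seqid, t$start), ]
    t[!duplicated(t$gene_id), ]
  }
  a <- pick(species_a); b <- pick(species_b)
  common <- intersect(a$gene_id, b$gene_id)
  a <- a[match(common, a$gene_id), ]; b <- b[match(common, b$gene_id), ]
  data.frame(gene_a = a$gene_id, seqid_a = a$seqid, start_a = a$start, end_a = a$end,
             gene_b = b$gene_id, seqid_b = b$seqid, start_b = b$start, end_b = b$end,
             stringsAsFactors = FALSE)
}

.gap_between <- function(s1, e1, s2, e2) pmax(0, pmax(s1, s2) - pmin(e1, e2))

#' Chain ortholog pairs into synteny blocks
#'
#' Two pairs belong to the same block when they lie on the same chromosome
#' in both species and within `join_distance` of each other (gap between
#' gene extents) in both species; blocks are the transitive closure of that
#' relation. The result is a partition of the input pairs, invariant to
#' input order, and the number of blocks is non-increasing in
#' `join_distance`.
#'
#' @param pairs data.frame from [ortholog_pairs()] (must be 1:1).
#' @param join_distance maximum gap (bp) in both species (default 50000).
#' @return data.frame, one row per block: block_id, n_genes, seqid_a,
#'   seqid_b, span_a_bp, span_b_bp, plus a `members` list-column of gene
#'   ids ordered by species-A position.
#' @export
chain_blocks <- function(pairs, join_distance = 50000) {
  n <- nrow(pairs)
  if (n == 0)
    return(data.frame(block_id = integer(), n_genes = integer(),
                      seqid_a = character(), seqid_b = character(),
                      span_a_bp = numeric(), span_b_bp = numeric()))
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b))
    stop("pairs must be 1:1 (deduplicate with ortholog_pairs first)")
  o <- order(pairs$seqid_a, pairs$start_a, pairs$gene_a)
  p <- pairs[o, ]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  # sorted sweep: pairs farther apart than join_distance in A cannot join
  for (i in seq_len(n - 1)) {
    j <- i + 1
    while (j <= n && p$seqid_a[j] == p$seqid_a[i] &&
           .gap_between(p$start_a[i], p$end_a[i], p$start_a[j], p$end_a[j]) <= join_distance) {
      if (p$seqid_b[j] == p$seqid_b[i] &&
          .gap_between(p$start_b[i], p$end_b[i], p$start_b[j], p$end_b[j]) <= join_distance) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
      j <- j + 1
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  ids <- match(comp, unique(comp))
  rows <- lapply(seq_len(max(ids)), function(b) {
    m <- p[ids == b, , drop = FALSE]
    data.frame(block_id = b, n_genes = nrow(m),
               seqid_a = m$seqid_a[1], seqid_b = m$seqid_b[1],
               span_a_bp = max(m$end_a) - min(m$start_a),
               span_b_bp = max(m$end_b) - min(m$start_b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(seq_len(max(ids)), function(b) p$gene_a[ids == b])
  out
}

#' Drop single-gene interchromosomal translocations
#'
#' Removes size-1 blocks whose two positions lie on non-homologous
#' chromosomes. Multi-gene blocks are never removed (the chaining rule
#' cannot produce a multi-gene block spanning chromosomes; this is
#' asserted).
#'
#' @param blocks data.frame from [chain_blocks()].
#' @param homology_map optional named character mapping species-A seqids to
#'   their homologous species-B seqids; by default homology is seqid-name
#'   equality.
#' @return filtered blocks, with attribute `n_removed`.
#' @export
filter_single_translocations <- function(blocks, homology_map = NULL) {
  homolog_b <- if (is.null(homology_map)) blocks$seqid_a
               else unname(homology_map[blocks$seqid_a])
  same <- !is.na(homolog_b) & homolog_b == blocks$seqid_b
  drop <- blocks$n_genes == 1 & !same
  out <- blocks[!drop, , drop = FALSE]
  if (sum(drop)) message(sum(drop), " single-gene translocation(s) removed")
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Fraction of ortholog pairs retained on homologous chromosomes
#'
#' @param pairs data.frame from [ortholog_pairs()].
#' @param homology_map named character species-A seqid -> homologous
#'   species-B seqid; defaults to name equality for all observed seqids.
#' @return list: `retention` (fraction), `n_same`, `n_total` (pairs with a
#'   mapped chromosome), `n_unassigned`, and a per-chromosome breakdown.
#' @export
chromosome_retention <- function(pairs, homology_map = NULL) {
  if (nrow(pairs) == 0) stop("no ortholog pairs")
  if (is.null(homology_map)) {
    sq <- unique(pairs$seqid_a)
    homology_map <- stats::setNames(sq, sq)
  }
  mapped_b <- unname(homology_map[pairs$seqid_a])
  unassigned <- is.na(mapped_b)
  if (any(unassigned))
    message(sum(unassigned), " pair(s) on unmapped chromosomes excluded")
  same <- !unassigned & mapped_b == pairs$seqid_b
  denom <- sum(!unassigned)
  per_chr <- tapply(same[!unassigned], pairs$seqid_a[!unassigned], mean)
  list(retention = sum(same) / denom, n_same = sum(same), n_total = denom,
       n_unassigned = sum(unassigned), per_chromosome = per_chr)
}

#' Scan for ortholog-poor (divergent) regions
#'
#' Slides windows along each scaffold; windows whose fraction of
#' ortholog-bearing genes is at most `max_density` (gene-free windows count
#' as ortholog-free) are merged into maximal runs, and runs of at least
#' `min_length_bp` are reported with their total gene and ortholog counts.
#'
#' @param annotation a `genome_annotation` for the focal species.
#' @param pairs ortholog pairs (only `gene_a` is used: the focal species'
#'   ortholog-bearing genes).
#' @param window_bp window size (bp).
#' @param min_length_bp minimum merged region length to report.
#' @param max_density maximum ortholog-bearing gene fraction in a window.
#' @param step_bp slide step; default `window_bp / 2`.
#' @return data.frame seqid, start, end, length_bp, n_genes, n_orthologs.
#' @export
divergent_regions <- function(annotation, pairs, window_bp = 100000,
                              min_length_bp = 500000, max_density = 0.1,
                              step_bp = NULL) {
  stopifnot(window_bp > 0)
  if (is.null(step_bp)) step_bp <- max(1, floor(window_bp / 2))
  g <- annotation$genes
  has_orth <- g$gene_id %in% pairs$gene_a
  mid <- (g$start + g$end) / 2
  out <- list()
  for (sq in names(annotation$seq_lengths)) {
    len <- annotation$seq_lengths[[sq]]
    if (len < window_bp) next
    starts <- seq(0, max(0, len - window_bp), by = step_bp)
    gm <- mid[g$seqid == sq]
    go <- has_orth[g$seqid == sq]
    n_in <- vapply(starts, function(s) sum(gm >= s & gm < s + window_bp), 0)
    o_in <- vapply(starts, function(s) sum(go[gm >= s & gm < s + window_bp]), 0)
    frac <- ifelse(n_in > 0, o_in / n_in, 0)
    low <- frac <= max_density
    if (!any(low)) next
    r <- rle(low)
    endsi <- cumsum(r$lengths); startsi <- endsi - r$lengths + 1
    for (k in which(r$values)) {
      rs <- starts[startsi[k]]
      re <- min(len, starts[endsi[k]] + window_bp)
      if (re - rs < min_length_bp) next
      inr <- g$seqid == sq & mid >= rs & mid < re
      out[[length(out) + 1]] <- data.frame(
        seqid = sq, start = rs, end = re, length_bp = re - rs,
        n_genes = sum(inr), n_orthologs = sum(has_orth & inr),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seqid = character(), start = numeric(), end = numeric(),
                      length_bp = numeric(), n_genes = integer(),
                      n_orthologs = integer()))
  do.call(rbind, out)
}

#' Indel size bias between matched synteny blocks
#'
#' For each block with at least `min_members` genes, the log span ratio
#' r = ln(span_a / span_b) is computed; a one-sample Wilcoxon signed-rank
#' test of r against 0 asks whether one genome's blocks are systematically
#' smaller. Blocks with a zero span are excluded and counted.
#'
#' @param blocks data.frame from [chain_blocks()].
#' @param min_members minimum genes per block (default 2).
#' @return list of class `indel_bias`: `test` (an `arch_test`),
#'   `median_ratio` (median span_a/span_b), `log_ratios`, `n_blocks`,
#'   `n_excluded`, and a per-block table (spans and log ratio) for
#'   scatter-style reporting.
#' @export
indel_size_bias <- function(blocks, min_members = 2) {
  b <- blocks[blocks$n_genes >= min_members, , drop = FALSE]
  zero <- b$span_a_bp <= 0 | b$span_b_bp <= 0
  if (any(zero)) message(sum(zero), " block(s) with zero span excluded")
  b <- b[!zero, , drop = FALSE]
  if (nrow(b) < 5)
    stop("need >= 5 blocks with >= ", min_members, " members")
  r <- log(b$span_a_bp / b$span_b_bp)
  if (all(r == 0)) {
    t <- .new_test_result(0, NA, 1, "Wilcoxon signed rank test", "log span ratio",
                          degenerate = TRUE)
  } else {
    w <- suppressWarnings(stats::wilcox.test(r, mu = 0))
    t <- .new_test_result(unname(w$statistic), NA, w$p.value,
                          "Wilcoxon signed rank test", "log span ratio")
  }
  tab <- data.frame(block_id = b$block_id, n_genes = b$n_genes,
                    span_a_bp = b$span_a_bp, span_b_bp = b$span_b_bp,
                    log_ratio = r)
  structure(list(test = t, median_ratio = stats::median(b$span_a_bp / b$span_b_bp),
                 log_ratios = r, n_blocks = nrow(b), n_excluded = sum(zero),
                 per_block = tab), class = "indel_bias")
}

#' @export
print.indel_bias <- function(x, ...) {
  cat(sprintf("Indel size bias over %d blocks: median span ratio %.3f\n",
              x$n_blocks, x$median_ratio))
  print(x$test)
  invisible(x)
}
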