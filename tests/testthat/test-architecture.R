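test_that("intergenic gaps union overlapping genes first and skip flanks", {
  mk <- function(genes) genome_annotation(
    seq_lengths = c(s1 = 200),
    genes = data.frame(gene_id = paste0("g", seq_len(nrow(genes))), seqid = "s1",
                       start = genes$start, end = genes$end, strand = "+"),
    transcripts = data.frame(tx_id = paste0("g", seq_len(nrow(genes)), ".t"),
                             gene_id = paste0("g", seq_len(nrow(genes))),
                             seqid = "s1", start = genes$start, end = genes$end,
                             strand = "+"),
    exons = data.frame(tx_id = paste0("g", seq_len(nrow(genes)), ".t"),
                       seqid = "s1", start = genes$start, end = genes$end))
  expect_equal(intergenic_spaces(mk(data.frame(start = c(10, 60), end = c(40, 80)))),
               20)
  # overlapping genes merge before gaps are measured
  expect_equal(intergenic_spaces(mk(data.frame(start = c(10, 30, 90),
                                               end = c(40, 70, 95)))), 20)
  # a single gene leaves no intergenic space (flanks excluded)
  expect_equal(intergenic_spaces(mk(data.frame(start = 10, end = 40))), numeric())
})

test_that("generated intergenic gaps recover their log-normal median", {
  p <- architecture_params(n_genes = 5000, n_scaffolds = 4, fraction_x = 0,
                           repeat_density = 0,
                           gap_meanlog = c(autosome = log(1000), X = log(1000)),
                           species = list(sp = list(gene_loss = 0,
                                                    intron_scale = c(autosome = 1, X = 1),
                                                    translocation_rate = 0)),
                           seed = 404)
  ann <- simulate_genomes(p)$species$sp$annotation
  gaps <- intergenic_spaces(ann)
  expect_gt(length(gaps), 4000)
  expect_lt(abs(median(gaps) - 1000) / 1000, 0.05)
})

test_that("gene metrics use the canonical transcript", {
  # 3 exons of 100/150/200 with introns 50/60; CDS of 303 bp
  ex_st <- c(0, 150, 360)
  ex_en <- ex_st + c(100, 150, 200)
  ann <- genome_annotation(
    seq_lengths = c(s1 = 1000),
    genes = data.frame(gene_id = "g1", seqid = "s1", start = 0, end = 560,
                       strand = "+"),
    transcripts = data.frame(tx_id = "t1", gene_id = "g1", seqid = "s1",
                             start = 0, end = 560, strand = "+"),
    exons = data.frame(tx_id = "t1", seqid = "s1", start = ex_st, end = ex_en),
    cds = data.frame(tx_id = "t1", seqid = "s1", start = c(50, 150),
                     end = c(100, 403)))
  m <- gene_metrics(ann)
  expect_equal(m$exon_sum_bp, 450)
  expect_equal(m$intron_sum_bp, 110)
  expect_equal(m$span_bp, 560)
  expect_equal(m$exon_count, 3)
  expect_equal(m$protein_aa, 100)  # 303 / 3 - 1
  # a gene with no CDS keeps size metrics but has no protein length
  ann2 <- toy_annotation()
  m2 <- gene_metrics(ann2)
  expect_true(is.na(m2$protein_aa))
  expect_equal(m2$span_bp, 30)
})

test_that("canonical transcript is largest summed-exon with lexicographic ties", {
  ann <- toy_annotation(alt = TRUE)   # t1 has 20 exonic bp, t2 has 10
  expect_equal(canonical_transcripts(ann)$tx_id, "t1")
})

test_that("Kruskal-Wallis H matches the hand-derived value for {1,2,3} vs {4,5,6}", {
  t <- kruskal_wallis(list(a = 1:3, b = 4:6))
  # ranks 1..6 fully separated: H = 12/(6*7) * (6.75 + 6.75) = 27/7
  expect_equal(t$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(round(t$statistic, 3), 3.857)
  expect_equal(t$df, 1)
  expect_equal(t$p_raw, stats::pchisq(27 / 7, 1, lower.tail = FALSE))
})

test_that("degenerate all-tied input gives H = 0, p = 1, flagged", {
  t <- kruskal_wallis(list(rep(2, 5), rep(2, 4)))
  expect_equal(t$statistic, 0)
  expect_equal(t$p_raw, 1)
  expect_true(t$degenerate)
  expect_error(kruskal_wallis(list(1, numeric())), "observation")
})

test_that("two-group H equals the squared tie-corrected normal rank-sum statistic", {
  set.seed(99)
  for (rep in 1:5) {
    x <- round(rlnorm(25, 5, 1)); y <- round(rlnorm(30, 5.3, 1))
    t <- kruskal_wallis(list(x, y))
    n <- length(x) + length(y)
    r <- rank(c(x, y))
    ties <- table(r)
    sigma2 <- (length(x) * length(y) / 12) *
      (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (sum(r[seq_along(x)]) - length(x) * (n + 1) / 2) / sqrt(sigma2)
    expect_equal(t$statistic, z^2, tolerance = 1e-10)
  }
})

test_that("pairwise Wilcoxon applies Bonferroni over all pairs", {
  set.seed(5)
  g <- list(a = rnorm(12), b = rnorm(12, 2), c = rnorm(12, 4))
  pw <- pairwise_wilcoxon(g)
  expect_equal(nrow(pw), 3)           # 3 groups -> 3 pairs, m = 3
  expect_equal(pw$p_adjusted, pmin(1, pw$p_raw * 3))
  expect_true(all(diff(pw$p_adjusted[order(pw$p_raw)]) >= 0))
  expect_true(all(pw$p_adjusted <= 1))
  # identical groups -> all adjusted p = 1
  same <- pairwise_wilcoxon(list(a = rep(1, 4), b = rep(1, 4), c = rep(1, 4)))
  expect_true(all(same$p_adjusted == 1))
  # empty group skipped with warning
  expect_warning(pw2 <- pairwise_wilcoxon(list(a = 1:3, b = numeric(), c = 4:6)),
                 "skipped")
  expect_equal(nrow(pw2), 1)
})

test_that("compare_architecture runs the full battery and handles degenerate input", {
  p <- architecture_params(n_genes = 200, n_scaffolds = 4, fraction_x = 0.5,
                           repeat_density = 0, seed = 31)
  sim <- simulate_genomes(p)
  anns <- lapply(sim$species, `[[`, "annotation")
  rep <- compare_architecture(anns, orthologs = sim$orthologs)
  expect_s3_class(rep, "architecture_report")
  expect_equal(nrow(rep$summary), 4)  # 2 species x 2 classes
  expect_true(all(c("intergenic", "gene_size", "protein_size") %in%
                  rep$within_species$measure))
  expect_true(all(rep$within_species$p_raw >= 0 & rep$within_species$p_raw <= 1))
  # ortholog filter restricts to genes present in both species
  expect_equal(rep$n_ortholog_filter,
               length(intersect(anns[[1]]$genes$gene_id, anns[[2]]$genes$gene_id)))
  # one gene per scaffold: no intergenic spaces; comparison skipped, not an error
  one <- genome_annotation(
    seq_lengths = c(a = 100, b = 100),
    genes = data.frame(gene_id = c("g1", "g2"), seqid = c("a", "b"),
                       start = 10, end = 40, strand = "+"),
    transcripts = data.frame(tx_id = c("t1", "t2"), gene_id = c("g1", "g2"),
                             seqid = c("a", "b"), start = 10, end = 40,
                             strand = "+"),
    exons = data.frame(tx_id = c("t1", "t2"), seqid = c("a", "b"),
                       start = 10, end = 40),
    chrom_class = c(a = "autosome", b = "X"))
  expect_message(rep1 <- compare_architecture(list(sp = one)), "skipping")
  expect_equal(rep1$summary$n_intergenic, c(0, 0))
})

test_that("scaffold length = gene-span union + gaps + flanks, per scaffold", {
  ann <- rand_annotation(seed = 23, n_genes = 40)
  g <- iv_union(gene_spans(ann))
  for (sq in unique(g$seqid)) {
    gi <- g[g$seqid == sq, ]
    gaps <- if (nrow(gi) > 1) sum(gi$start[-1] - gi$end[-nrow(gi)]) else 0
    flanks <- gi$start[1] + (ann$seq_lengths[[sq]] - gi$end[nrow(gi)])
    expect_equal(iv_total(gi) + gaps + flanks, ann$seq_lengths[[sq]])
  }
})
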