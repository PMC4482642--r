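test_that("site classes follow the precedence order", {
  # gene on +: exons [100,200)+[300,400); CDS [120,380) within exons;
  # UTR5 [100,120), UTR3 [380,400); TE overlapping the CDS and the TSS window
  ann <- genome_annotation(
    seq_lengths = c(s1 = 1000),
    genes = data.frame(gene_id = "g1", seqid = "s1", start = 100, end = 400,
                       strand = "+"),
    transcripts = data.frame(tx_id = "t1", gene_id = "g1", seqid = "s1",
                             start = 100, end = 400, strand = "+"),
    exons = data.frame(tx_id = "t1", seqid = "s1", start = c(100, 300),
                       end = c(200, 400)),
    cds = data.frame(tx_id = "t1", seqid = "s1", start = c(120, 300),
                     end = c(200, 380)),
    utr5 = data.frame(tx_id = "t1", seqid = "s1", start = 100, end = 120),
    utr3 = data.frame(tx_id = "t1", seqid = "s1", start = 380, end = 400),
    repeats = interval_set("s1", c(150, 0, 500), c(260, 50, 560)))
  cmap <- classify_sites(ann, tss_window_bp = 200)
  # base inside CDS and TE -> CDS_exon wins
  expect_equal(lookup_class(cmap, "s1", 160), "CDS_exon")
  # intron outranks TE inside the gene body
  expect_equal(lookup_class(cmap, "s1", 270), "intron")
  expect_equal(lookup_class(cmap, "s1", 210), "intron")
  # a repeat in otherwise intergenic DNA is TE
  expect_equal(lookup_class(cmap, "s1", 520), "TE")
  # 100 bp upstream of the + strand TSS, within the 200-bp window
  expect_equal(lookup_class(cmap, "s1", 20), "TSS")
  # TE that also sits in the TSS window loses to TSS (precedence)
  expect_equal(lookup_class(cmap, "s1", 10), "TSS")
  expect_equal(lookup_class(cmap, "s1", 600), "intergenic")
  expect_true(is.na(lookup_class(cmap, "sX", 5)))
  # the map partitions the genome
  expect_equal(sum(cmap$totals), sum(ann$seq_lengths))
})

test_that("TSS windows are strand-aware and clipped", {
  ann <- genome_annotation(
    seq_lengths = c(s1 = 500),
    genes = data.frame(gene_id = "g1", seqid = "s1", start = 50, end = 450,
                       strand = "-"),
    transcripts = data.frame(tx_id = "t1", gene_id = "g1", seqid = "s1",
                             start = 50, end = 450, strand = "-"),
    exons = data.frame(tx_id = "t1", seqid = "s1", start = 50, end = 450))
  cmap <- classify_sites(ann, tss_window_bp = 200)
  # minus-strand TSS window is downstream in genomic coordinates, clipped at 500
  expect_equal(lookup_class(cmap, "s1", 460), "TSS")
  expect_equal(iv_total(cmap$class_map$TSS), 50)
})

test_that("class totals match a per-base bitmap oracle on random genomes", {
  for (seed in c(5, 29)) {
    ann <- rand_annotation(seed = seed, n_genes = 25, repeat_density = 0.2)
    cmap <- classify_sites(ann, tss_window_bp = 150)
    sl <- ann$seq_lengths
    expect_equal(sum(cmap$totals), sum(sl))
    # oracle: paint classes in reverse precedence so earlier classes overwrite
    paint <- lapply(sl, function(L) rep("intergenic", L))
    stamp <- function(tab, label) {
      for (r in seq_len(nrow(tab))) {
        sq <- tab$seqid[r]
        lo <- max(0, tab$start[r]); hi <- min(sl[[sq]], tab$end[r])
        if (hi > lo) paint[[sq]][(lo + 1):hi] <<- label
      }
    }
    stamp(ann$repeats, "TE")
    tx <- ann$transcripts
    plus <- tx$strand != "-"
    stamp(data.frame(seqid = tx$seqid,
                     start = ifelse(plus, tx$start - 150, tx$end),
                     end = ifelse(plus, tx$start, tx$end + 150)), "TSS")
    ex <- ann$exons
    o <- order(ex$tx_id, ex$start)
    exo <- ex[o, ]
    same <- c(FALSE, exo$tx_id[-1] == exo$tx_id[-nrow(exo)])
    stamp(data.frame(seqid = exo$seqid[-1][same[-1]],
                     start = exo$end[-nrow(exo)][same[-1]],
                     end = exo$start[-1][same[-1]]), "intron")
    stamp(ann$utr3, "UTR3")
    stamp(ann$utr5, "UTR5")
    stamp(ann$cds, "CDS_exon")
    oracle_totals <- table(factor(unlist(paint), levels = names(cmap$totals)))
    expect_equal(unname(cmap$totals[names(oracle_totals)]),
                 as.numeric(oracle_totals))
    # spot-check positions through lookup_class
    set.seed(seed)
    sq <- sample(names(sl), 200, replace = TRUE)
    pos <- floor(runif(200) * sl[sq])
    expect_equal(lookup_class(cmap, sq, pos),
                 unname(mapply(function(s, q) paint[[s]][q + 1], sq, pos)))
  }
})

test_that("polymorphism tallies apply the depth and quality filters exactly", {
  ann <- toy_annotation()
  cmap <- classify_sites(ann, tss_window_bp = 10)
  sites <- data.frame(seqid = "s1", pos = c(12, 14, 31, 25, 50, 60),
                      depth = c(100, 601, 100, 100, 600, 100),
                      base_quality = c(40, 40, 9.9, 40, 10, 40),
                      is_variant = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
                      dp_missing = FALSE)
  tal <- polymorphism_by_class(sites, cmap)
  tal_df <- as.data.frame(tal)
  # depth 601 and quality 9.9 are excluded from numerator AND denominator;
  # depth 600 and quality 10 are at the threshold edge and kept
  expect_equal(attr(tal, "n_filtered"), 2)
  expect_equal(sum(tal_df$assayed_sites), 4)
  expect_equal(sum(tal_df$polymorphic_sites), 2)
  # no-filter run equals raw counting; filters never increase assayed counts
  tal_raw <- polymorphism_by_class(sites, cmap, max_depth = Inf, min_quality = 0)
  expect_equal(sum(as.data.frame(tal_raw)$assayed_sites), nrow(sites))
  expect_true(all(as.data.frame(tal)$assayed_sites <=
                  as.data.frame(tal_raw)$assayed_sites))
  # simple percent arithmetic: 2 variants in 10,000 exonic sites = 0.02%
  big <- data.frame(seqid = "s1", pos = rep(12, 10000), depth = 50,
                    base_quality = 40, is_variant = FALSE, dp_missing = FALSE,
                    class = "CDS_exon")
  big$is_variant[1:2] <- TRUE
  talb <- polymorphism_by_class(big, cmap)
  expect_equal(as.data.frame(talb)$percent[1], 0.02)
})

test_that("generated VCF recovers the planted class rates", {
  p <- architecture_params(n_genes = 60, n_scaffolds = 3, seed = 15)
  ann <- simulate_genomes(p)$species$outcrosser$annotation
  gv <- generate_vcf(ann, c(CDS_exon = 0, UTR5 = 0, UTR3 = 0, intron = 0,
                            intergenic = 0), seed = 2)
  expect_equal(sum(gv$sites$is_variant), 0)  # rate 0 everywhere
  expect_equal(nrow(gv$sites), sum(ann$seq_lengths))
  # determinism
  gv2 <- generate_vcf(ann, c(intron = 0), seed = 2)
  expect_identical(gv$sites$depth, gv2$sites$depth)
  # rate recovery within 3 binomial SE at 1e-3 over intronic sites
  gv3 <- generate_vcf(ann, c(intron = 1e-3), seed = 6)
  intr <- gv3$sites[gv3$sites$class == "intron", ]
  se <- sqrt(1e-3 * (1 - 1e-3) / nrow(intr))
  expect_lt(abs(mean(intr$is_variant) - 1e-3), 3 * se)
  expect_error(generate_vcf(ann, c(bogus = 1e-4)), "unknown feature class")
  expect_error(generate_vcf(ann, c(intron = 0.2)), "0, 0.05")
})

test_that("marker QC drops distorted scaffolds, low representation and duplicates", {
  mk_marker <- function(n_a, n_miss = 0) {
    g <- rep(c("A", "B"), c(n_a, 64 - n_a))
    if (n_miss > 0) g[sample.int(64, n_miss)] <- "-"
    g
  }
  set.seed(33)
  g <- rbind(
    t(vapply(c(58, 59, 60, 61, 62, 63), mk_marker, character(64))),  # 90%+ A: scf1
    t(vapply(c(30, 32, 34, 36, 28, 26), mk_marker, character(64))),  # balanced scf2
    matrix(mk_marker(32, n_miss = 26), 1),                           # 38 lines only
    matrix(rep(c("B", "A"), each = 32), 1),                          # duplicate source
    matrix(rep(c("B", "A"), each = 32), 1))                          # duplicate
  rownames(g) <- sprintf("m%02d", seq_len(nrow(g)))
  smap <- stats::setNames(c(rep("scf1", 6), rep("scf2", 6), "scf3", "scf3", "scf3"),
                          rownames(g))
  qc <- marker_qc(g, smap, min_lines = 40)
  expect_equal(qc$input_markers, 15)
  expect_equal(qc$dropped_by_scaffold_distortion, 6)  # all six at 90% A
  expect_equal(qc$flagged_scaffolds, "scf1")
  expect_equal(qc$dropped_low_representation, 1)      # present in 38 < 40 lines
  expect_equal(qc$dropped_duplicate_only, 1)
  expect_equal(qc$retained_markers, 7)
  expect_equal(qc$input_markers,
               qc$retained_markers + qc$dropped_by_scaffold_distortion +
                 qc$dropped_low_representation + qc$dropped_duplicate_only)
  # exactly 5 flagged markers on a scaffold does NOT trigger removal (> 5 rule)
  g5 <- g[1:5, , drop = FALSE]
  qc5 <- marker_qc(g5, smap[1:5], min_lines = 40)
  expect_equal(qc5$dropped_by_scaffold_distortion, 0)

  # idempotence: re-running on the retained output changes nothing
  g_kept <- g[qc$retained, , drop = FALSE]
  qc2 <- marker_qc(g_kept, smap, min_lines = 40)
  expect_equal(qc2$retained, qc$retained)
  expect_equal(qc2$dropped_by_scaffold_distortion +
                 qc2$dropped_low_representation + qc2$dropped_duplicate_only, 0)
})

test_that("generated RIL genotypes carry the planted distortion", {
  sim <- generate_ril_genotypes(64, 60, scaffold_map = rep(sprintf("s%d", 1:10), 6),
                                distorted_scaffolds = c("s1", "s2"),
                                distortion_level = 0.9, missing_rate = 0,
                                seed = 12)
  expect_false(any(sim$genotypes == "-"))  # missing_rate 0
  freq_a <- apply(sim$genotypes, 1, function(r)
    sum(r == "A") / sum(r %in% c("A", "B")))
  dist <- sim$scaffold_map %in% c("s1", "s2")
  # binomial error around the planted frequencies
  expect_lt(abs(mean(freq_a[dist]) - 0.9), 3 * sqrt(0.9 * 0.1 / (64 * sum(dist))))
  expect_lt(abs(mean(freq_a[!dist]) - 0.5), 3 * sqrt(0.25 / (64 * sum(!dist))))
  qc <- marker_qc(sim$genotypes, sim$scaffold_map, min_lines = 40)
  expect_setequal(qc$flagged_scaffolds, c("s1", "s2"))
  expect_error(generate_ril_genotypes(1, 5, "s"), "2 lines")
  expect_error(generate_ril_genotypes(10, 5, "s", distortion_level = 0.4),
               "0.5, 1")
})
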