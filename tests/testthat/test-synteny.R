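mk_pairs <- function(start_a, start_b, seqid_a = "cA", seqid_b = "cB",
                     len = 500) {
  n <- length(start_a)
  data.frame(gene_a = sprintf("a%02d", seq_len(n)),
             seqid_a = rep_len(seqid_a, n), start_a = start_a,
             end_a = start_a + len,
             gene_b = sprintf("b%02d", seq_len(n)),
             seqid_b = rep_len(seqid_b, n), start_b = start_b,
             end_b = start_b + len, stringsAsFactors = FALSE)
}

# O(n^2) transitive chaining oracle, independent of chain_blocks
oracle_partition <- function(pairs, join) {
  n <- nrow(pairs)
  gap <- function(s1, e1, s2, e2) max(0, max(s1, s2) - min(e1, e2))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    adj[i, j] <- pairs$seqid_a[i] == pairs$seqid_a[j] &&
      pairs$seqid_b[i] == pairs$seqid_b[j] &&
      gap(pairs$start_a[i], pairs$end_a[i], pairs$start_a[j], pairs$end_a[j]) <= join &&
      gap(pairs$start_b[i], pairs$end_b[i], pairs$start_b[j], pairs$end_b[j]) <= join
  }
  comp <- rep(NA_integer_, n); cid <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1; queue <- i; comp[i] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid; queue <- c(queue, nb)
    }
  }
  unname(lapply(split(pairs$gene_a, comp), sort))
}

canon_partition <- function(members) {
  out <- lapply(members, sort)
  out[order(vapply(out, `[`, "", 1))]
}

random_pairs <- function(n, seed) {
  set.seed(seed)
  chrs <- c("c1", "c2")
  sa <- sample(chrs, n, replace = TRUE)
  # mostly syntenic, some translocated
  sb <- ifelse(runif(n) < 0.9, sa, sample(chrs, n, replace = TRUE))
  mk <- function(s) floor(runif(n) * 4e5)
  p <- mk_pairs(mk(), mk(), seqid_a = sa, seqid_b = sb,
                len = 200 + floor(runif(n) * 2000))
  p$start_b <- floor(runif(n) * 4e5)
  p$end_b <- p$start_b + 200 + floor(runif(n) * 2000)
  p
}

test_that("chain_blocks reproduces the hand-traced example", {
  p <- mk_pairs(c(1e3, 3e4, 1e5), c(2e3, 3.5e4, 3.8e4))
  bl <- chain_blocks(p, join_distance = 50000)
  expect_equal(nrow(bl), 2)  # A-gap of ~70 kb splits g3 off
  expect_equal(canon_partition(bl$members),
               canon_partition(list(c("a01", "a02"), "a03")))
  # single pair -> one block of size 1
  b1 <- chain_blocks(mk_pairs(100, 100))
  expect_equal(b1$n_genes, 1)
  expect_equal(b1$span_a_bp, 500)
})

test_that("chain_blocks equals the O(n^2) transitive-chaining oracle", {
  for (seed in c(2, 9, 33, 77)) {
    p <- random_pairs(150, seed)
    bl <- chain_blocks(p, join_distance = 50000)
    expect_equal(canon_partition(bl$members),
                 canon_partition(oracle_partition(p, 50000)))
  }
})

test_that("chaining is order-invariant and partitions the input", {
  p <- random_pairs(100, 4)
  bl1 <- chain_blocks(p, 30000)
  set.seed(1)
  bl2 <- chain_blocks(p[sample.int(nrow(p)), ], 30000)
  expect_equal(canon_partition(bl1$members), canon_partition(bl2$members))
  # partition: every pair in exactly one block
  all_members <- unlist(bl1$members)
  expect_equal(sort(all_members), sort(p$gene_a))
  # duplicated pairs are rejected
  expect_error(chain_blocks(rbind(p, p)), "1:1")
})

test_that("block count is non-increasing in join_distance", {
  p <- random_pairs(120, 11)
  counts <- vapply(c(1e3, 1e4, 5e4, 2e5, 1e6),
                   function(j) nrow(chain_blocks(p, j)), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("single-gene translocations are removed, syntenic singletons kept", {
  p <- mk_pairs(c(1e3, 5e5), c(1e3, 5e5))
  p$seqid_b[2] <- "cOther"   # lone pair on a non-homologous chromosome
  bl <- chain_blocks(p, 50000)
  expect_message(kept <- filter_single_translocations(
    bl, homology_map = c(cA = "cB")), "1 single-gene")
  expect_equal(nrow(kept), 1)
  expect_equal(kept$seqid_b, "cB")
  expect_equal(attr(kept, "n_removed"), 1)
  # with homology by name equality nothing matches "cB" so both would go
  bl2 <- chain_blocks(mk_pairs(1e3, 1e3, seqid_a = "c1", seqid_b = "c1"))
  expect_equal(nrow(filter_single_translocations(bl2)), 1)
})

test_that("chromosome retention counts homologous placements", {
  p <- mk_pairs(c(1, 100, 200) * 1e3, c(1, 100, 200) * 1e3,
                seqid_a = "c1", seqid_b = "c1")
  expect_equal(chromosome_retention(p)$retention, 1)
  p$seqid_b[3] <- "c2"
  ret <- chromosome_retention(p)
  expect_equal(ret$retention, 2 / 3)
  # unmapped chromosomes drop out of the denominator
  p$seqid_a[2] <- "cUnknown"
  expect_message(ret2 <- chromosome_retention(p, homology_map = c(c1 = "c1")),
                 "unmapped")
  expect_equal(ret2$n_total, 2)
  expect_equal(ret2$retention, 1 / 2)
  expect_error(chromosome_retention(p[0, ]), "no ortholog pairs")
})

test_that("divergent region scan finds ortholog deserts and nothing else", {
  ann <- rand_annotation(seed = 55, n_genes = 120, n_scaffolds = 2,
                         repeat_density = 0)
  pairs <- data.frame(gene_a = ann$genes$gene_id)
  # uniform orthology: nothing reported
  expect_equal(nrow(divergent_regions(ann, pairs, window_bp = 1e5,
                                      min_length_bp = 3e5, max_density = 0.1)), 0)
  # whole scaffold ortholog-free: one region spanning (nearly) the scaffold
  sq <- names(ann$seq_lengths)[1]
  empty <- pairs[!(pairs$gene_a %in% ann$genes$gene_id[ann$genes$seqid == sq]), ,
                 drop = FALSE]
  dr <- divergent_regions(ann, empty, window_bp = 1e5, min_length_bp = 3e5,
                          max_density = 0.1)
  expect_equal(unique(dr$seqid), sq)
  expect_gte(max(dr$end) - min(dr$start), 0.9 * ann$seq_lengths[[sq]])
  expect_equal(sum(dr$n_orthologs), 0)
})

test_that("indel size bias behaves on constructed span ratios", {
  bl <- data.frame(block_id = 1:6, n_genes = 3,
                   span_a_bp = c(10, 20, 30, 40, 50, 60) * 1e3)
  bl$span_b_bp <- bl$span_a_bp
  res <- indel_size_bias(bl)
  expect_equal(res$median_ratio, 1)
  expect_equal(res$test$p_raw, 1)
  expect_true(all(res$log_ratios == 0))
  # spans_b = 2 * spans_a: systematic shrinkage detected at n = 6
  bl$span_b_bp <- 2 * bl$span_a_bp
  res2 <- indel_size_bias(bl)
  expect_equal(res2$median_ratio, 0.5)
  expect_lt(res2$test$p_raw, 0.05)
  # distinct ratios, all < 1: exact signed-rank two-sided p = 2/2^6
  bl$span_b_bp <- bl$span_a_bp * seq(1.8, 2.3, by = 0.1)
  res3 <- indel_size_bias(bl)
  expect_equal(res3$test$p_raw, 2 / 64)
  # zero-span blocks are excluded with a message; too few blocks errors
  bl$span_b_bp[1:2] <- 0
  expect_error(expect_message(indel_size_bias(bl), "zero span"), ">= 5")
})

test_that("indel bias p-values are calibrated under symmetric noise", {
  set.seed(12)
  ps <- replicate(200, {
    spans_a <- rlnorm(12, 10, 0.5)
    spans_b <- spans_a * rlnorm(12, 0, 0.3)
    bl <- data.frame(block_id = 1:12, n_genes = 2,
                     span_a_bp = spans_a, span_b_bp = spans_b)
    indel_size_bias(bl)$test$p_raw
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
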