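## Brute-force per-base / per-read oracles, independent of the package's
## interval and k-mer machinery, plus small fixture builders.

# per-base occupancy bitmap (TRUE where covered), one logical vector per seqid
bitmap_cover <- function(iv, seq_lengths) {
  out <- lapply(names(seq_lengths), function(sq) {
    v <- logical(seq_lengths[[sq]])
    rows <- iv[iv$seqid == sq, , drop = FALSE]
    for (r in seq_len(nrow(rows)))
      v[(rows$start[r] + 1):rows$end[r]] <- TRUE
    v
  })
  names(out) <- names(seq_lengths)
  out
}

bitmap_total <- function(bm) sum(vapply(bm, sum, 0))

random_intervals <- function(n, seq_lengths) {
  sq <- sample(names(seq_lengths), n, replace = TRUE)
  len <- unname(seq_lengths[sq])
  start <- floor(runif(n) * (len - 1))
  end <- pmin(len, start + 1 + floor(rexp(n, 1 / 50)))
  interval_set(sq, start, end)
}

# the 100-bp toy: one gene with exons [10,20) and [30,40), one transcript
toy_annotation <- function(alt = FALSE) {
  exons <- data.frame(tx_id = "t1", seqid = "s1", start = c(10, 30), end = c(20, 40))
  tx <- data.frame(tx_id = "t1", gene_id = "g1", seqid = "s1",
                   start = 10, end = 40, strand = "+")
  if (alt) {
    tx <- rbind(tx, data.frame(tx_id = "t2", gene_id = "g1", seqid = "s1",
                               start = 10, end = 40, strand = "+"))
    exons <- rbind(exons, data.frame(tx_id = "t2", seqid = "s1", start = 10, end = 20))
  }
  genome_annotation(
    seq_lengths = c(s1 = 100),
    genes = data.frame(gene_id = "g1", seqid = "s1", start = 10, end = 40,
                       strand = "+"),
    transcripts = tx, exons = exons)
}

# small random annotation via the generator (no repeats for speed unless asked)
rand_annotation <- function(seed, n_genes = 40, n_scaffolds = 3,
                            repeat_density = 0.1, fraction_x = 0.34) {
  p <- architecture_params(n_genes = n_genes, n_scaffolds = n_scaffolds,
                           fraction_x = fraction_x,
                           repeat_density = repeat_density, seed = seed)
  simulate_genomes(p)$species$outcrosser$annotation
}

# test-local reverse complement and canonical form (independent of the package)
oracle_revcomp <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = ""),
    "", USE.NAMES = FALSE)
}
oracle_canonical <- function(s) {
  rc <- oracle_revcomp(s)
  ifelse(s <= rc, s, rc)
}
oracle_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  km <- substring(s, 1:(n - k + 1), k:n)
  km[!grepl("[^ACGT]", km)]
}
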