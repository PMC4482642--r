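#' Parameters for the synthetic multi-species genome generator
#'
#' Defaults emulate the architecture contrasts seen between outcrossing and
#' self-fertile Caenorhabditis: genes with ~6 exons of ~200 bp, heavy-tailed
#' (log-normal) intron and intergenic length distributions whose medians
#' differ between autosome-like and X-like scaffolds, a selfing-derived
#' species that has lost a fraction of the ancestral genes together with
#' their flanking intergenic DNA and carries X-specific intron expansion,
#' planted repeats, and occasional interchromosomal translocations.
#'
#' @param n_genes ancestral gene count.
#' @param n_scaffolds number of scaffolds; the first
#'   `round(fraction_x * n_scaffolds)` are labelled class "X".
#' @param fraction_x fraction of scaffolds labelled X.
#' @param exon_count_mean mean exons per gene (1 + Poisson).
#' @param exon_len_meanlog,exon_len_sdlog log-normal exon length parameters
#'   (defaults give mean ~200 bp).
#' @param intron_meanlog named (autosome, X) log-medians of intron length.
#' @param intron_sdlog log-normal sd of intron lengths.
#' @param gap_meanlog named (autosome, X) log-medians of intergenic gaps.
#' @param gap_sdlog log-normal sd of intergenic gaps.
#' @param utr5_len,utr3_len typical UTR lengths (log-normal medians).
#' @param alt_splice_frac fraction of genes with a second transcript that
#'   skips one internal exon (drives summed > union footprints).
#' @param repeat_density target fraction of each scaffold covered by
#'   planted repeats.
#' @param te_families number of repeat families.
#' @param gc GC fraction of emitted sequence.
#' @param species named list; each element a list with `gene_loss`
#'   (fraction of ancestral genes deleted, with their downstream gap),
#'   `intron_scale` (named c(autosome=, X=) multipliers) and
#'   `translocation_rate` (fraction of surviving genes moved to a different
#'   scaffold).
#' @param seed integer seed; fixing it fixes every output.
#' @return list of class `architecture_params`.
#' @export
architecture_params <- function(
    n_genes = 2000,
    n_scaffolds = 10,
    fraction_x = 0.2,
    exon_count_mean = 6,
    exon_len_meanlog = log(180), exon_len_sdlog = 0.45,
    intron_meanlog = c(autosome = log(800), X = log(1200)),
    intron_sdlog = 1.0,
    gap_meanlog = c(autosome = log(1000), X = log(1800)),
    gap_sdlog = 1.2,
    utr5_len = 100, utr3_len = 150,
    alt_splice_frac = 0.10,
    repeat_density = 0.15,
    te_families = 5,
    gc = 0.36,
    species = list(
      outcrosser = list(gene_loss = 0,
                        intron_scale = c(autosome = 1, X = 1),
                        translocation_rate = 0),
      selfer = list(gene_loss = 0.2,
                    intron_scale = c(autosome = 1, X = 1.5),
                    translocation_rate = 0.05)),
    seed = 1L) {
  p <- as.list(environment())
  fr <- c(fraction_x, repeat_density, alt_splice_frac, gc,
          vapply(species, function(s) s$gene_loss, 0),
          vapply(species, function(s) s$translocation_rate, 0))
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (n_genes < 1 || n_scaffolds < 1) stop("need at least one gene and scaffold")
  if (any(!is.finite(c(exon_len_meanlog, intron_meanlog, gap_meanlog))) ||
      exon_len_sdlog < 0 || intron_sdlog < 0 || gap_sdlog < 0)
    stop("distribution parameters must yield positive lengths")
  class(p) <- "architecture_params"
  p
}

.rlen <- function(n, meanlog, sdlog, minimum) {
  if (n == 0) return(numeric())
  pmax(minimum, round(stats::rlnorm(n, meanlog, sdlog)))
}

## Draw per-gene structures for the ancestor.
.sim_structures <- function(p, classes) {
  n <- length(classes)
  n_ex <- pmax(1L, 1L + stats::rpois(n, p$exon_count_mean - 1))
  lapply(seq_len(n), function(i) {
    ex <- .rlen(n_ex[i], p$exon_len_meanlog, p$exon_len_sdlog, 20)
    inr <- .rlen(n_ex[i] - 1, p$intron_meanlog[[classes[i]]], p$intron_sdlog, 5)
    tot <- sum(ex)
    u5 <- min(.rlen(1, log(p$utr5_len), 0.3, 10), max(0, floor((tot - 9) / 3)))
    u3 <- min(.rlen(1, log(p$utr3_len), 0.3, 10), max(0, floor((tot - 9) / 3)))
    u3 <- u3 + (tot - u5 - u3) %% 3  # CDS length a codon multiple
    drop <- NA_integer_
    if (n_ex[i] >= 3 && stats::runif(1) < p$alt_splice_frac)
      drop <- sample(2:(n_ex[i] - 1), 1)
    list(exons = ex, introns = inr, u5 = u5, u3 = u3,
         strand = sample(c("+", "-"), 1), alt_drop = drop)
  })
}

## Split a sorted exon chain at transcript-chain offsets into
## left UTR / CDS / right UTR genomic pieces (vectors, not frames: this
## runs once per gene).
.split_exons <- function(starts, ends, left_trim, right_trim) {
  lens <- ends - starts
  total <- sum(lens)
  off <- cumsum(c(0, lens[-length(lens)]))
  clip <- function(lo, hi) {
    s <- pmax(lo, off); e <- pmin(hi, off + lens)
    k <- e > s
    list(start = starts[k] + (s[k] - off[k]),
         end = starts[k] + (e[k] - off[k]))
  }
  list(left = clip(0, left_trim),
       cds = clip(left_trim, total - right_trim),
       right = clip(total - right_trim, total))
}

## Lay out one species' genes on scaffolds and build the annotation.
## Accumulates plain vectors (one data.frame build at the end) so genomes
## of several thousand genes simulate in seconds.
.build_annotation <- function(tbl, scaffolds, chrom_class, flanks, p) {
  G <- list(gene_id = list(), seqid = list(), start = list(), end = list(),
            strand = list())
  TX <- list(tx_id = list(), gene_id = list(), seqid = list(), start = list(),
             end = list(), strand = list())
  child_acc <- function() list(tx_id = list(), seqid = list(),
                               start = list(), end = list())
  EX <- child_acc(); CD <- child_acc(); U5 <- child_acc(); U3 <- child_acc()
  push_child <- function(A, tid, sc, s, e) {
    if (!length(s)) return(A)
    i <- length(A$tx_id) + 1L
    A$tx_id[[i]] <- rep(tid, length(s)); A$seqid[[i]] <- rep(sc, length(s))
    A$start[[i]] <- s; A$end[[i]] <- e
    A
  }
  seq_lengths <- stats::setNames(numeric(length(scaffolds)), scaffolds)
  k <- 0L
  for (sc in scaffolds) {
    rows <- tbl[tbl$scaffold == sc, , drop = FALSE]
    rows <- rows[order(rows$ord), , drop = FALSE]
    pos <- flanks[[sc]]
    for (i in seq_len(nrow(rows))) {
      st <- rows$structure[[i]]
      k <- k + 1L
      ex_st <- pos + cumsum(c(0, st$exons[-length(st$exons)] + st$introns))
      ex_en <- ex_st + st$exons
      span_end <- ex_en[length(ex_en)]
      gid <- rows$gene_id[i]
      tid <- paste0(gid, ".t1")
      G$gene_id[[k]] <- gid; G$seqid[[k]] <- sc; G$start[[k]] <- pos
      G$end[[k]] <- span_end; G$strand[[k]] <- st$strand
      j <- length(TX$tx_id) + 1L
      TX$tx_id[[j]] <- tid; TX$gene_id[[j]] <- gid; TX$seqid[[j]] <- sc
      TX$start[[j]] <- pos; TX$end[[j]] <- span_end; TX$strand[[j]] <- st$strand
      EX <- push_child(EX, tid, sc, ex_st, ex_en)
      left <- if (st$strand == "+") st$u5 else st$u3
      right <- if (st$strand == "+") st$u3 else st$u5
      sp <- .split_exons(ex_st, ex_en, left, right)
      CD <- push_child(CD, tid, sc, sp$cds$start, sp$cds$end)
      uL <- if (st$strand == "+") sp$left else sp$right
      uR <- if (st$strand == "+") sp$right else sp$left
      U5 <- push_child(U5, tid, sc, uL$start, uL$end)
      U3 <- push_child(U3, tid, sc, uR$start, uR$end)
      if (!is.na(st$alt_drop)) {
        tid2 <- paste0(gid, ".t2")
        keep <- setdiff(seq_along(st$exons), st$alt_drop)
        j <- length(TX$tx_id) + 1L
        TX$tx_id[[j]] <- tid2; TX$gene_id[[j]] <- gid; TX$seqid[[j]] <- sc
        TX$start[[j]] <- pos; TX$end[[j]] <- span_end; TX$strand[[j]] <- st$strand
        EX <- push_child(EX, tid2, sc, ex_st[keep], ex_en[keep])
      }
      pos <- span_end + rows$gap[i]
    }
    seq_lengths[sc] <- pos
  }
  flat <- function(A) {
    n <- length(A[[1]])
    if (!n) return(NULL)
    as.data.frame(lapply(A, function(col) unlist(col, use.names = FALSE)),
                  stringsAsFactors = FALSE)
  }
  gene_rows <- list(flat(G)); tx_rows <- list(flat(TX))
  ex_rows <- list(flat(EX)); cds_rows <- list(flat(CD))
  u5_rows <- list(flat(U5)); u3_rows <- list(flat(U3))
  bindup <- function(l) {
    l <- l[!vapply(l, is.null, TRUE)]
    if (!length(l)) return(NULL)
    do.call(rbind, l)
  }
  # plant repeats
  rep_rows <- lapply(scaffolds, function(sc) {
    len <- seq_lengths[[sc]]
    target <- p$repeat_density * len
    if (target < 50) return(NULL)
    lens <- numeric(); tot <- 0
    while (tot < target) {
      l <- .rlen(1, log(300), 0.7, 50)
      lens <- c(lens, l); tot <- tot + l
    }
    starts <- sort(sample.int(max(1, len - max(lens)), length(lens), replace = TRUE)) - 1
    data.frame(seqid = sc, start = starts, end = pmin(len, starts + lens),
               family = paste0("TE", sample.int(p$te_families, length(lens),
                                                replace = TRUE)))
  })
  repeats <- bindup(rep_rows)
  genome_annotation(
    seq_lengths = seq_lengths,
    genes = bindup(gene_rows),
    transcripts = bindup(tx_rows),
    exons = bindup(ex_rows),
    cds = bindup(cds_rows), utr5 = bindup(u5_rows), utr3 = bindup(u3_rows),
    repeats = if (is.null(repeats)) NULL else
      structure(repeats, class = c("interval_set", "data.frame")),
    chrom_class = chrom_class)
}

#' Generate synthetic multi-species genomes with known ground truth
#'
#' Simulates an ancestral gene complement, then derives each configured
#' species by (1) deleting `gene_loss` of the genes together with their
#' downstream intergenic gap, (2) scaling intron lengths per chromosome
#' class, and (3) translocating a fraction of surviving genes to a
#' different scaffold. Orthology between species is recorded for genes
#' surviving in both (orthologous genes share their ancestral gene id).
#'
#' @param params an [architecture_params()] object.
#' @param emit_sequence if `TRUE`, i.i.d. random sequence at the configured
#'   GC is attached per species (needed for read simulation and GC
#'   profiling; slow for large genomes).
#' @return object of class `synthetic_genomes`: list with `species` (name ->
#'   list(annotation, sequence)), `orthologs` (long table, one row per gene
#'   per species keyed by ancestral gene id), and `truth` (per-species
#'   deleted/translocated gene sets, chromosome classes, parameters).
#' @export
simulate_genomes <- function(params, emit_sequence = FALSE) {
  stopifnot(inherits(params, "architecture_params"))
  set.seed(params$seed)
  p <- params
  scaffolds <- sprintf("scf%02d", seq_len(p$n_scaffolds))
  n_x <- round(p$fraction_x * p$n_scaffolds)
  chrom_class <- stats::setNames(
    c(rep("X", n_x), rep("autosome", p$n_scaffolds - n_x)), scaffolds)
  per <- rep(floor(p$n_genes / p$n_scaffolds), p$n_scaffolds)
  left <- p$n_genes - sum(per)
  if (left > 0) per[seq_len(left)] <- per[seq_len(left)] + 1
  scaff_of_gene <- rep(scaffolds, per)
  classes <- chrom_class[scaff_of_gene]
  structures <- .sim_structures(p, classes)
  gaps <- vapply(seq_len(p$n_genes), function(i)
    .rlen(1, p$gap_meanlog[[classes[i]]], p$gap_sdlog, 1), 0)
  flanks <- stats::setNames(lapply(scaffolds, function(sc)
    .rlen(1, p$gap_meanlog[[chrom_class[[sc]]]], p$gap_sdlog, 1)), scaffolds)
  anc <- data.frame(gene_id = sprintf("g%05d", seq_len(p$n_genes)),
                    scaffold = scaff_of_gene,
                    ord = seq_len(p$n_genes),
                    gap = gaps, stringsAsFactors = FALSE)
  anc$structure <- structures

  species <- list()
  truth <- list(chrom_class = chrom_class, params = p, species = list())
  for (sp_name in names(p$species)) {
    cfg <- p$species[[sp_name]]
    tbl <- anc
    # class-specific intron scaling
    scl <- cfg$intron_scale
    tbl$structure <- lapply(seq_len(nrow(tbl)), function(i) {
      st <- tbl$structure[[i]]
      s <- scl[[chrom_class[[tbl$scaffold[i]]]]]
      if (s != 1) st$introns <- pmax(1, round(st$introns * s))
      st
    })
    # gene loss (deterministic count, stochastic choice)
    n_del <- round(cfg$gene_loss * nrow(tbl))
    deleted <- if (n_del > 0) sample(tbl$gene_id, n_del) else character()
    tbl <- tbl[!(tbl$gene_id %in% deleted), , drop = FALSE]
    # translocations
    n_tr <- round(cfg$translocation_rate * nrow(tbl))
    moved <- if (n_tr > 0) sample(tbl$gene_id, n_tr) else character()
    if (n_tr > 0) {
      idx <- match(moved, tbl$gene_id)
      for (j in idx) {
        others <- setdiff(scaffolds, tbl$scaffold[j])
        tbl$scaffold[j] <- sample(others, 1)
        tbl$ord[j] <- max(tbl$ord) + j  # appended at scaffold end
      }
    }
    ann <- .build_annotation(tbl, scaffolds, chrom_class, flanks, p)
    seqs <- NULL
    if (emit_sequence) {
      seqs <- Biostrings::DNAStringSet(vapply(names(ann$seq_lengths), function(sc)
        paste(sample(c("A", "C", "G", "T"), ann$seq_lengths[[sc]], replace = TRUE,
                     prob = c((1 - p$gc) / 2, p$gc / 2, p$gc / 2, (1 - p$gc) / 2)),
              collapse = ""), ""))
      names(seqs) <- names(ann$seq_lengths)
    }
    species[[sp_name]] <- list(annotation = ann, sequence = seqs)
    truth$species[[sp_name]] <- list(deleted = sort(deleted),
                                     translocated = sort(moved))
  }
  ortho <- do.call(rbind, lapply(names(species), function(sp_name) {
    g <- species[[sp_name]]$annotation$genes
    data.frame(gene_id = g$gene_id, species = sp_name, seqid = g$seqid,
               start = g$start, end = g$end, stringsAsFactors = FALSE)
  }))
  ortho <- ortho[order(ortho$gene_id, ortho$species), ]
  structure(list(species = species, orthologs = ortho, truth = truth),
            class = "synthetic_genomes")
}

#' @export
print.synthetic_genomes <- function(x, ...) {
  cat("synthetic_genomes with", length(x$species), "species:\n")
  for (nm in names(x$species)) {
    ann <- x$species[[nm]]$annotation
    cat(sprintf("  %s: %d genes, %s bp\n", nm, nrow(ann$genes),
                format(sum(ann$seq_lengths), big.mark = ",")))
  }
  invisible(x)
}

#' Write a synthetic genome set to a directory
#'
#' Emits, per species, a GFF3 annotation, a repeats BED, a chromosome-class
#' TSV and (if sequence was generated) a FASTA; plus the shared ortholog TSV
#' and a `manifest.json` naming every file and the seed.
#'
#' @param sim a `synthetic_genomes` object.
#' @param dir output directory (created if needed).
#' @return the manifest as a list, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (nm in names(sim$species)) {
    ann <- sim$species[[nm]]$annotation
    gff <- file.path(dir, paste0(nm, ".gff3"))
    write_gff3(ann, gff)
    bed <- file.path(dir, paste0(nm, ".repeats.bed"))
    write_bed(ann$repeats, bed)
    cls <- file.path(dir, paste0(nm, ".classes.tsv"))
    utils::write.table(data.frame(seqid = names(ann$chrom_class),
                                  class = unname(ann$chrom_class)),
                       cls, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[nm]] <- list(gff3 = gff, repeats = bed, classes = cls)
    if (!is.null(sim$species[[nm]]$sequence)) {
      fa <- file.path(dir, paste0(nm, ".fa"))
      write_fasta(sim$species[[nm]]$sequence, fa)
      files[[nm]]$fasta <- fa
    }
  }
  ortho <- file.path(dir, "orthologs.tsv")
  write_orthologs(sim$orthologs, ortho)
  manifest <- list(seed = sim$truth$params$seed,
                   species = files, orthologs = ortho)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate paired-end reads from a genome
#'
#' Uniform fragment sampling with per-base substitution errors and an
#' optional contaminant read fraction; read 2 is the reverse complement of
#' the fragment's other end. Qualities are a constant Phred+33 'I'.
#'
#' @param fasta named `DNAStringSet` (or character vector) of scaffolds.
#' @param coverage target fold coverage of the target genome.
#' @param read_len read length (bp).
#' @param fragment_len fragment length; default `2 * read_len` (abutting
#'   mates). Scaffolds shorter than the fragment are skipped with a warning.
#' @param error_rate per-base substitution probability.
#' @param contaminant_fasta optional contaminant scaffolds.
#' @param contaminant_fraction fraction of read pairs drawn from the
#'   contaminant.
#' @param seed integer seed.
#' @return list with `r1`, `r2` (`DNAStringSet`s) and `is_contaminant`
#'   (logical per pair).
#' @export
generate_reads <- function(fasta, coverage = 30, read_len = 100,
                           fragment_len = NULL, error_rate = 0.001,
                           contaminant_fasta = NULL, contaminant_fraction = 0,
                           seed = 1L) {
  stopifnot(coverage > 0, read_len >= 20)
  if (is.null(fragment_len)) fragment_len <- 2L * read_len
  stopifnot(fragment_len >= read_len)
  set.seed(seed)
  if (!methods::is(fasta, "DNAStringSet")) fasta <- Biostrings::DNAStringSet(fasta)
  lens <- Biostrings::width(fasta)
  usable <- lens >= fragment_len
  if (!all(usable))
    warning(sum(!usable), " scaffold(s) shorter than fragment length skipped")
  if (!any(usable)) stop("no scaffold long enough for fragment length")
  genome_len <- sum(lens[usable])
  n_pairs <- max(1L, round(coverage * genome_len / (2 * read_len)))
  n_cont <- round(contaminant_fraction * n_pairs)
  sample_pairs <- function(ss, n) {
    w <- Biostrings::width(ss)
    ok <- which(w >= fragment_len)
    sc <- ok[sample.int(length(ok), n, replace = TRUE,
                        prob = w[ok] - fragment_len + 1)]
    pos <- floor(stats::runif(n) * (w[sc] - fragment_len + 1)) + 1
    frag <- as.character(Biostrings::subseq(ss[sc], start = pos,
                                            width = fragment_len))
    r1 <- substr(frag, 1, read_len)
    r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
      substr(frag, fragment_len - read_len + 1, fragment_len))))
    list(r1 = r1, r2 = r2)
  }
  tgt <- sample_pairs(fasta[usable], n_pairs - n_cont)
  is_cont <- rep(FALSE, n_pairs - n_cont)
  if (n_cont > 0) {
    if (is.null(contaminant_fasta)) stop("contaminant_fraction > 0 needs contaminant_fasta")
    if (!methods::is(contaminant_fasta, "DNAStringSet"))
      contaminant_fasta <- Biostrings::DNAStringSet(contaminant_fasta)
    cnt <- sample_pairs(contaminant_fasta, n_cont)
    tgt$r1 <- c(tgt$r1, cnt$r1); tgt$r2 <- c(tgt$r2, cnt$r2)
    is_cont <- c(is_cont, rep(TRUE, n_cont))
  }
  add_errors <- function(reads) {
    n_err <- stats::rbinom(length(reads), read_len, error_rate)
    hit <- which(n_err > 0)
    for (i in hit) {
      pos <- sample.int(read_len, n_err[i])
      for (q in pos) {
        cur <- substr(reads[i], q, q)
        substr(reads[i], q, q) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      }
    }
    reads
  }
  if (error_rate > 0) {
    tgt$r1 <- add_errors(tgt$r1)
    tgt$r2 <- add_errors(tgt$r2)
  }
  ids <- sprintf("pair%07d", seq_along(tgt$r1))
  r1 <- Biostrings::DNAStringSet(tgt$r1); names(r1) <- paste0(ids, "/1")
  r2 <- Biostrings::DNAStringSet(tgt$r2); names(r2) <- paste0(ids, "/2")
  list(r1 = r1, r2 = r2, is_contaminant = is_cont)
}

#' Simulate an all-sites VCF over an annotated genome
#'
#' Every base of the genome is an assayed site. Variant (residual
#' heterozygosity) status is Bernoulli at the per-feature-class rate; site
#' depths follow a negative-binomial model, and small fractions of sites are
#' planted with depth > 600 or quality < Q10 to exercise the site filters.
#'
#' @param annotation a `genome_annotation`.
#' @param per_class_het_rate named numeric; names from
#'   CDS_exon, UTR5, UTR3, intron, TSS, TE, intergenic (missing classes get
#'   rate 0). Rates must lie in [0, 0.05].
#' @param depth_model list(mean, overdispersion): depth ~ NB with mean
#'   `mean` and size `mean / overdispersion`.
#' @param high_depth_frac fraction of sites planted with depth > 600.
#' @param low_qual_frac fraction of sites planted with quality < Q10.
#' @param tss_window_bp TSS window used for site classification.
#' @param seed integer seed.
#' @param path if given, the VCF is also written there.
#' @return list with `sites` (data.frame as from [read_vcf_sites()], plus a
#'   `class` column), `class_rates`, and `path`.
#' @export
generate_vcf <- function(annotation, per_class_het_rate,
                         depth_model = list(mean = 60, overdispersion = 0.5),
                         high_depth_frac = 0.002, low_qual_frac = 0.002,
                         tss_window_bp = 200, seed = 1L, path = NULL) {
  classes <- c("CDS_exon", "UTR5", "UTR3", "intron", "TSS", "TE", "intergenic")
  if (length(setdiff(names(per_class_het_rate), classes)))
    stop("unknown feature class: ",
         paste(setdiff(names(per_class_het_rate), classes), collapse = ", "))
  if (any(per_class_het_rate < 0 | per_class_het_rate > 0.05))
    stop("heterozygosity rates must lie in [0, 0.05]")
  rates <- stats::setNames(rep(0, length(classes)), classes)
  rates[names(per_class_het_rate)] <- per_class_het_rate
  set.seed(seed)
  cmap <- classify_sites(annotation, tss_window_bp = tss_window_bp)
  tabs <- lapply(classes, function(cl) {
    iv <- cmap$class_map[[cl]]
    if (is.null(iv) || nrow(iv) == 0) return(NULL)
    pos <- unlist(mapply(function(s, e) s:(e - 1), iv$start, iv$end,
                         SIMPLIFY = FALSE), use.names = FALSE)
    data.frame(seqid = rep(iv$seqid, iv$end - iv$start), pos = pos,
               class = cl, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, tabs[!vapply(tabs, is.null, TRUE)])
  sites <- sites[order(sites$seqid, sites$pos), ]
  n <- nrow(sites)
  sites$is_variant <- stats::runif(n) < rates[sites$class]
  size <- depth_model$mean / max(depth_model$overdispersion, 1e-6)
  sites$depth <- stats::rnbinom(n, mu = depth_model$mean, size = size)
  hi <- stats::runif(n) < high_depth_frac
  sites$depth[hi] <- 601 + stats::rnbinom(sum(hi), mu = 400, size = 5)
  sites$base_quality <- round(stats::runif(n, 25, 60), 1)
  lo <- stats::runif(n) < low_qual_frac
  sites$base_quality[lo] <- round(stats::runif(sum(lo), 0, 9.9), 1)
  sites$dp_missing <- FALSE
  rownames(sites) <- NULL
  if (!is.null(path)) write_vcf_sites(sites, path, annotation$seq_lengths)
  list(sites = sites, class_rates = rates, path = path)
}

#' Simulate RIL genotype matrices with planted segregation distortion
#'
#' Markers on distorted scaffolds have parental-A allele frequency
#' `distortion_level`; all others 0.5. Residual heterozygous calls and
#' missing data are applied i.i.d.
#'
#' @param n_lines number of recombinant inbred lines (>= 2).
#' @param n_markers number of markers.
#' @param scaffold_map character vector (length `n_markers`, or a single
#'   set of scaffold names recycled round-robin) assigning markers to
#'   scaffolds.
#' @param distorted_scaffolds scaffolds whose markers are distorted.
#' @param distortion_level parental-A frequency on distorted scaffolds,
#'   in (0.5, 1].
#' @param missing_rate i.i.d. missing-call probability.
#' @param het_rate i.i.d. residual-heterozygote probability.
#' @param seed integer seed.
#' @return list: `genotypes` (marker x line character matrix of A/B/H/-),
#'   `scaffold_map` (named marker -> scaffold), `distorted_scaffolds`.
#' @export
generate_ril_genotypes <- function(n_lines, n_markers, scaffold_map,
                                   distorted_scaffolds = character(),
                                   distortion_level = 0.9,
                                   missing_rate = 0.02, het_rate = 0.02,
                                   seed = 1L) {
  if (n_lines < 2) stop("need at least 2 lines")
  if (distortion_level <= 0.5 || distortion_level > 1)
    stop("distortion_level must lie in (0.5, 1]")
  set.seed(seed)
  if (length(scaffold_map) < n_markers)
    scaffold_map <- rep(scaffold_map, length.out = n_markers)
  scaffold_map <- scaffold_map[seq_len(n_markers)]
  markers <- sprintf("m%05d", seq_len(n_markers))
  names(scaffold_map) <- markers
  pA <- ifelse(scaffold_map %in% distorted_scaffolds, distortion_level, 0.5)
  g <- matrix("B", n_markers, n_lines,
              dimnames = list(markers, sprintf("line%03d", seq_len(n_lines))))
  a_draw <- matrix(stats::runif(n_markers * n_lines) < pA, n_markers, n_lines)
  g[a_draw] <- "A"
  g[matrix(stats::runif(n_markers * n_lines) < het_rate, n_markers, n_lines)] <- "H"
  g[matrix(stats::runif(n_markers * n_lines) < missing_rate, n_markers, n_lines)] <- "-"
  list(genotypes = g, scaffold_map = scaffold_map,
       distorted_scaffolds = distorted_scaffolds)
}
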