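## Readers/writers for the plain-text formats the pipeline consumes.
## GFF3 and VCF are 1-based closed on disk; everything returned here is
## 0-based half-open.

.parse_gff_attrs <- function(s) {
  out <- lapply(strsplit(s, ";", fixed = TRUE), function(kv) {
    kv <- kv[nzchar(kv)]
    parts <- regmatches(kv, regexpr("=", kv), invert = TRUE)
    vals <- vapply(parts, function(p) if (length(p) == 2) p[2] else NA_character_, "")
    names(vals) <- vapply(parts, `[`, "", 1)
    vals
  })
  out
}

#' Read a GFF3 gene annotation
#'
#' Parses gene / mRNA / exon / CDS / UTR features into a
#' [genome_annotation()]. Coordinates are converted from GFF3's 1-based
#' closed convention to the package's 0-based half-open convention. A
#' trailing `##FASTA` section is ignored. Genes without any transcript are
#' dropped with a warning; a child feature naming an unknown parent is a
#' consistency error.
#'
#' @param path GFF3 file.
#' @param seq_lengths named numeric seqid -> length. If `NULL`, taken from
#'   `##sequence-region` pragmas (required then).
#' @param chrom_class optional named character seqid -> class, passed through.
#' @param repeats optional repeat interval set, passed through.
#' @return a `genome_annotation`.
#' @export
read_gff3 <- function(path, seq_lengths = NULL, chrom_class = NULL, repeats = NULL) {
  lines <- readLines(path)
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at)) lines <- lines[seq_len(fasta_at[1] - 1)]
  pragma <- startsWith(lines, "#")
  if (is.null(seq_lengths)) {
    sr <- lines[startsWith(lines, "##sequence-region")]
    if (!length(sr)) stop("seq_lengths not given and no ##sequence-region pragmas")
    parts <- strsplit(trimws(sr), "\\s+")
    seq_lengths <- vapply(parts, function(p) as.numeric(p[4]), 0)
    names(seq_lengths) <- vapply(parts, `[`, "", 2)
  }
  body_idx <- which(!pragma & nzchar(lines))
  if (!length(body_idx)) stop("GFF3 has no feature lines")
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9))
    stop("GFF3 parse error: expected 9 tab-separated columns at line ",
         body_idx[which(nf != 9)[1]])
  tab <- data.frame(
    seqid = vapply(fields, `[`, "", 1),
    type = vapply(fields, `[`, "", 3),
    start = as.numeric(vapply(fields, `[`, "", 4)) - 1,  # to 0-based
    end = as.numeric(vapply(fields, `[`, "", 5)),
    strand = vapply(fields, `[`, "", 7),
    stringsAsFactors = FALSE)
  attrs <- .parse_gff_attrs(vapply(fields, `[`, "", 9))
  tab$ID <- vapply(attrs, function(a) if ("ID" %in% names(a)) a[["ID"]] else NA_character_, "")
  tab$Parent <- vapply(attrs, function(a) if ("Parent" %in% names(a)) a[["Parent"]] else NA_character_, "")

  is_tx <- tab$type %in% c("mRNA", "transcript")
  genes <- tab[tab$type == "gene", ]
  txs <- tab[is_tx, ]
  if (nrow(txs) && !all(txs$Parent %in% genes$ID))
    stop("GFF3 consistency error: transcript with unknown gene parent: ",
         txs$ID[which(!(txs$Parent %in% genes$ID))[1]])
  pick_children <- function(types) {
    ch <- tab[tab$type %in% types, ]
    if (!nrow(ch)) return(data.frame(tx_id = character(), seqid = character(),
                                     start = numeric(), end = numeric()))
    if (!all(ch$Parent %in% txs$ID))
      stop("GFF3 consistency error: ", types[1], " with unknown parent: ",
           ch$Parent[which(!(ch$Parent %in% txs$ID))[1]])
    data.frame(tx_id = ch$Parent, seqid = ch$seqid,
               start = ch$start, end = ch$end, stringsAsFactors = FALSE)
  }
  exons <- pick_children("exon")
  cds <- pick_children("CDS")
  utr5 <- pick_children("five_prime_UTR")
  utr3 <- pick_children("three_prime_UTR")

  orphan <- !(genes$ID %in% txs$Parent)
  if (any(orphan)) {
    warning(sum(orphan), " gene(s) without transcripts dropped")
    genes <- genes[!orphan, ]
  }
  genome_annotation(
    seq_lengths = seq_lengths,
    genes = data.frame(gene_id = genes$ID, seqid = genes$seqid,
                       start = genes$start, end = genes$end,
                       strand = genes$strand, stringsAsFactors = FALSE),
    transcripts = data.frame(tx_id = txs$ID, gene_id = txs$Parent,
                             seqid = txs$seqid, start = txs$start,
                             end = txs$end, strand = txs$strand,
                             stringsAsFactors = FALSE),
    exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
    repeats = repeats, chrom_class = chrom_class)
}

#' Write a genome annotation as GFF3
#'
#' Inverse of [read_gff3()]: emits `##sequence-region` pragmas and
#' gene/mRNA/exon/CDS/UTR features in 1-based closed coordinates.
#'
#' @param ann a `genome_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d",
                     names(ann$seq_lengths), as.integer(ann$seq_lengths)), con)
  fmt <- function(seqid, type, start, end, strand, attr)
    sprintf("%s\tgenarch\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, type, as.integer(start) + 1L, as.integer(end), strand, attr)
  g <- ann$genes
  tx <- ann$transcripts
  tx_strand <- stats::setNames(tx$strand, tx$tx_id)
  rows <- rbind(
    if (nrow(g)) data.frame(seqid = g$seqid, type = "gene", start = g$start,
                            end = g$end, strand = g$strand,
                            attr = paste0("ID=", g$gene_id),
                            key = g$seqid, pos = g$start, sub = 0,
                            stringsAsFactors = FALSE),
    if (nrow(tx)) data.frame(seqid = tx$seqid, type = "mRNA", start = tx$start,
                             end = tx$end, strand = tx$strand,
                             attr = paste0("ID=", tx$tx_id, ";Parent=", tx$gene_id),
                             key = tx$seqid, pos = tx$start, sub = 1,
                             stringsAsFactors = FALSE))
  child_rows <- function(tab, type) {
    if (is.null(tab) || !nrow(tab)) return(NULL)
    data.frame(seqid = tab$seqid, type = type, start = tab$start, end = tab$end,
               strand = as.character(tx_strand[tab$tx_id]),
               attr = paste0("Parent=", tab$tx_id),
               key = tab$seqid, pos = tab$start, sub = 2,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(rows, child_rows(ann$exons, "exon"), child_rows(ann$cds, "CDS"),
                child_rows(ann$utr5, "five_prime_UTR"),
                child_rows(ann$utr3, "three_prime_UTR"))
  rows <- rows[order(rows$key, rows$pos, rows$sub, -rows$end), ]
  writeLines(fmt(rows$seqid, rows$type, rows$start, rows$end, rows$strand,
                 rows$attr), con)
  invisible(path)
}

#' Read repeat annotations from BED3/BED6
#'
#' BED is already 0-based half-open; columns beyond the third are kept as
#' `family` (column 4) when present.
#'
#' @param path BED file.
#' @return an `interval_set` (with `family` column for BED6).
#' @export
read_repeats_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED needs at least 3 columns")
  iv <- interval_set(tab[[1]], tab[[2]], tab[[3]])
  if (ncol(tab) >= 4) iv$family <- as.character(tab[[4]])
  iv
}

#' Write an interval set as BED
#' @param iv interval set; optional `family` column becomes BED column 4.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  iv <- as.data.frame(iv)
  cols <- sprintf("%s\t%d\t%d", iv$seqid, as.integer(iv$start), as.integer(iv$end))
  if ("family" %in% names(iv)) cols <- paste0(cols, "\t", iv$family)
  writeLines(cols, path)
  invisible(path)
}

#' Read per-site records from a VCF
#'
#' Returns one row per VCF record with 0-based position, site depth (INFO
#' `DP`, falling back to the first sample's FORMAT `DP`), the site QUAL as
#' base quality, and whether the record is a variant (ALT other than ".").
#' Records without a usable DP are kept but flagged (`dp_missing`); callers
#' doing depth filtering exclude them, and the count is messaged.
#'
#' @param path VCF v4.x file (plain or gzipped).
#' @return data.frame seqid, pos, depth, base_quality, is_variant, dp_missing.
#' @export
read_vcf_sites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  dp <- suppressWarnings(vcfR::extract.info(v, "DP", as.numeric = TRUE))
  if (all(is.na(dp)) && ncol(v@gt) > 1) {
    gt_dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
    dp <- as.numeric(gt_dp[, 1])
  }
  flagged <- sum(is.na(dp))
  if (flagged > 0) message(flagged, " VCF record(s) lack DP and are flagged")
  alt <- fix[, "ALT"]
  data.frame(
    seqid = fix[, "CHROM"],
    pos = as.numeric(fix[, "POS"]) - 1,
    depth = dp,
    base_quality = suppressWarnings(as.numeric(fix[, "QUAL"])),
    is_variant = !is.na(alt) & alt != "." & nzchar(alt),
    dp_missing = is.na(dp),
    stringsAsFactors = FALSE)
}

#' Write a minimal all-sites VCF
#'
#' @param sites data.frame with seqid, pos (0-based), depth, base_quality,
#'   is_variant (and optionally ref/alt columns).
#' @param path output file (".gz" suffix writes gzipped).
#' @param seq_lengths optional named vector for contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf_sites <- function(sites, path, seq_lengths = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total Depth">')
  if (!is.null(seq_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(seq_lengths), as.integer(seq_lengths)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(hdr, con)
  ref <- if ("ref" %in% names(sites)) sites$ref else "A"
  alt <- if ("alt" %in% names(sites)) sites$alt else ifelse(sites$is_variant, "T", ".")
  info <- ifelse(is.na(sites$depth), ".", sprintf("DP=%d", as.integer(sites$depth)))
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s",
                     sites$seqid, as.integer(sites$pos) + 1L, ref, alt,
                     ifelse(is.na(sites$base_quality), ".",
                            format(sites$base_quality, trim = TRUE)),
                     info), con)
  invisible(path)
}

#' Read an ortholog position table
#'
#' Expected header: `gene_id species seqid start end` (tab-separated,
#' 0-based half-open coordinates). Rows sharing a `gene_id` across species
#' form one ortholog group.
#'
#' @param path TSV file.
#' @return data.frame with those five columns.
#' @export
read_orthologs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "species", "seqid", "start", "end")
  if (!all(need %in% names(tab)))
    stop("ortholog table must have columns: ", paste(need, collapse = " "))
  tab[need]
}

#' Write an ortholog position table
#' @param tab data.frame as returned by [read_orthologs()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_orthologs <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a RIL genotype matrix
#'
#' Markers in rows, lines in columns; entries A/B/H/- (parental A, parental
#' B, heterozygous, missing).
#'
#' @param path TSV with a `marker` first column.
#' @return character matrix, rownames = marker ids.
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  bad <- !(m %in% c("A", "B", "H", "-"))
  if (any(bad)) stop("genotype matrix has entries outside A/B/H/-")
  m
}

#' Write a RIL genotype matrix
#' @param m character matrix as from [read_genotypes()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(m, path) {
  tab <- data.frame(marker = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read FASTA sequences
#' @param path FASTA file.
#' @return a `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write FASTA sequences
#' @param seqs named `DNAStringSet` or named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ (Phred+33), plain or gzipped.
#' @return `DNAStringSet` with qualities in `mcols(x)$qualities`.
#' @export
read_fastq <- function(path)
  Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)

#' Write a FASTQ file
#' @param seqs named `DNAStringSet`; qualities taken from
#'   `mcols(seqs)$qualities` or a constant Phred+33 'I' if absent.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  quals <- S4Vectors::mcols(seqs)$qualities
  if (is.null(quals))
    quals <- Biostrings::BStringSet(vapply(Biostrings::width(seqs), function(w)
      paste(rep("I", w), collapse = ""), ""))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}
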