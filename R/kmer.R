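## Two-pass k-mer spectrum read filter: pass 1 counts canonical k-mers over
## the whole read set, pass 2 drops reads with too many singleton k-mers
## (likely sequencing errors) or too many highly abundant k-mers (likely
## over-represented repeats).

.kmer_windows <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, 1:(n - k + 1), k:n)
}

.canonical_kmers <- function(kmers) {
  if (!length(kmers)) return(kmers)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

.as_read_chars <- function(x) {
  if (is.character(x) && length(x) >= 1 && all(file.exists(x))) {
    sets <- lapply(x, read_fastq)
    return(unlist(lapply(sets, as.character)))
  }
  if (methods::is(x, "DNAStringSet")) return(as.character(x))
  if (is.character(x)) return(x)
  stop("reads must be FASTQ path(s), a DNAStringSet or a character vector")
}

#' Build a canonical k-mer spectrum from reads
#'
#' Counts every ACGT-only window of length `k` in canonical
#' (strand-collapsed: lexicographic minimum of a k-mer and its reverse
#' complement) form. Windows containing N are skipped; reads shorter than
#' `k` contribute nothing and are counted in a message.
#'
#' @param reads FASTQ path(s), a `DNAStringSet`, or a character vector of
#'   read sequences. For the two-pass filter contract, pass the same reads
#'   here and to [filter_reads()].
#' @param k odd k-mer size >= 3 (default 15).
#' @return object of class `kmer_spectrum`: list(k, counts, total_kmers,
#'   distinct_kmers).
#' @export
build_spectrum <- function(reads, k = 15) {
  if (k < 3 || k %% 2 == 0) stop("k must be odd and >= 3")
  seqs <- toupper(.as_read_chars(reads))
  short <- sum(nchar(seqs) < k)
  if (short > 0) message(short, " read(s) shorter than k contribute no k-mers")
  km <- unlist(lapply(seqs, .kmer_windows, k = k), use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  counts <- table(.canonical_kmers(km))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(k = k, counts = counts,
                 total_kmers = sum(counts),
                 distinct_kmers = length(counts)),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum: k = %d, %s k-mers counted, %s distinct (%.1f%% singletons)\n",
              x$k, format(x$total_kmers, big.mark = ","),
              format(x$distinct_kmers, big.mark = ","),
              100 * mean(x$counts == 1)))
  invisible(x)
}

#' Save / load a k-mer spectrum sidecar file
#' @param spectrum a `kmer_spectrum`.
#' @param path TSV path (kmer, count).
#' @return `path` / the reloaded `kmer_spectrum`.
#' @export
save_spectrum <- function(spectrum, path) {
  utils::write.table(
    data.frame(kmer = names(spectrum$counts), count = spectrum$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_spectrum
#' @export
load_spectrum <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  counts <- stats::setNames(as.integer(tab$count), tab$kmer)
  structure(list(k = nchar(tab$kmer[1]), counts = counts,
                 total_kmers = sum(counts), distinct_kmers = length(counts)),
            class = "kmer_spectrum")
}

#' Read-filtering policy for the k-mer pre-filter
#'
#' Defaults mirror the assembly preprocessing rules: drop a read carrying
#' more than 12 singleton k-mers (likely errors) or more than 51 k-mers
#' occurring over 20,000 times in the dataset (over-represented repeats).
#'
#' @param max_singletons maximum allowed k-mers with count 1.
#' @param high_count_threshold a k-mer is "abundant" above this count.
#' @param max_high_count_kmers maximum allowed abundant k-mers per read.
#' @param pair_mode "drop_pair" removes both mates when either fails;
#'   "drop_read" removes reads independently.
#' @return list of class `filter_policy`.
#' @export
filter_policy <- function(max_singletons = 12, high_count_threshold = 20000,
                          max_high_count_kmers = 51,
                          pair_mode = c("drop_pair", "drop_read")) {
  if (max_singletons <= 0 || high_count_threshold <= 0 || max_high_count_kmers <= 0)
    stop("thresholds must be > 0")
  structure(list(max_singletons = max_singletons,
                 high_count_threshold = high_count_threshold,
                 max_high_count_kmers = max_high_count_kmers,
                 pair_mode = match.arg(pair_mode)), class = "filter_policy")
}

.read_failures <- function(seqs, spectrum, policy) {
  k <- spectrum$k
  km_list <- lapply(toupper(seqs), function(s) {
    km <- .kmer_windows(s, k)
    km[!grepl("[^ACGT]", km)]
  })
  idx <- rep(seq_along(km_list), lengths(km_list))
  flat <- .canonical_kmers(unlist(km_list, use.names = FALSE))
  cnt <- unname(spectrum$counts[flat])
  cnt[is.na(cnt)] <- 0L
  n <- length(seqs)
  tab_by <- function(v) {
    out <- numeric(n)
    if (length(idx)) {
      agg <- rowsum(as.numeric(v), idx)
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }
  n_singleton <- tab_by(cnt == 1)
  n_abundant <- tab_by(cnt > policy$high_count_threshold)
  list(singleton_fail = n_singleton > policy$max_singletons,
       abundant_fail = n_abundant > policy$max_high_count_kmers)
}

#' Filter a read pair set against a k-mer spectrum
#'
#' A read fails when its number of singleton k-mers exceeds
#' `max_singletons` OR its number of abundant k-mers (count above
#' `high_count_threshold`) exceeds `max_high_count_kmers`. Under
#' `pair_mode = "drop_pair"` both mates go when either fails. N-containing
#' k-mers neither count for nor against a read.
#'
#' @param r1,r2 mate sets: FASTQ paths, `DNAStringSet`s or character
#'   vectors of equal length.
#' @param spectrum `kmer_spectrum` built over the same read set.
#' @param policy a [filter_policy()].
#' @return list: `keep` (logical per pair/read), `r1`, `r2` (kept reads, as
#'   character), and `report` (reads in/out and failure-reason counts).
#' @export
filter_reads <- function(r1, r2, spectrum, policy = filter_policy()) {
  s1 <- .as_read_chars(r1); s2 <- .as_read_chars(r2)
  if (length(s1) != length(s2)) stop("mate sets differ in length")
  f1 <- .read_failures(s1, spectrum, policy)
  f2 <- .read_failures(s2, spectrum, policy)
  fail1 <- f1$singleton_fail | f1$abundant_fail
  fail2 <- f2$singleton_fail | f2$abundant_fail
  if (policy$pair_mode == "drop_pair") {
    keep <- !(fail1 | fail2)
    kept1 <- s1[keep]; kept2 <- s2[keep]
  } else {
    keep <- cbind(r1 = !fail1, r2 = !fail2)
    kept1 <- s1[!fail1]; kept2 <- s2[!fail2]
  }
  report <- list(
    reads_in = 2L * length(s1),
    reads_out = length(kept1) + length(kept2),
    failed_singleton = sum(f1$singleton_fail) + sum(f2$singleton_fail),
    failed_abundant = sum(f1$abundant_fail) + sum(f2$abundant_fail),
    pair_mode = policy$pair_mode)
  list(keep = keep, r1 = kept1, r2 = kept2, report = report)
}
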