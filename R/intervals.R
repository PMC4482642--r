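#' Genomic interval sets
#'
#' All coordinates inside the package are 0-based, half-open: an interval
#' covers bases `start, start+1, ..., end-1` and has length `end - start`.
#' GFF3 and VCF coordinates (1-based) are converted at the file boundary.
#' An interval set is a plain data.frame with columns `seqid`, `start`,
#' `end`; extra columns are carried along untouched by the constructor but
#' dropped by the algebra (union/complement/intersect collapse annotation).
#'
#' @param seqid character vector of sequence (scaffold) names.
#' @param start,end integer-like vectors; `end > start >= 0` per row.
#' @return A data.frame of class `interval_set`.
#' @examples
#' iv <- interval_set(c("chrI", "chrI"), c(0, 5), c(10, 15))
#' iv_total(iv_union(iv))  # 15
#' @export
interval_set <- function(seqid = character(), start = integer(), end = integer()) {
  x <- data.frame(seqid = as.character(seqid),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  class(x) <- c("interval_set", "data.frame")
  x
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("seqid", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0)) stop("interval start must be >= 0")
  if (any(x$end <= x$start)) stop("interval end must be > start")
  invisible(x)
}

as_interval_set <- function(x) {
  if (inherits(x, "interval_set")) return(x)
  interval_set(x$seqid, x$start, x$end)
}

## IRanges is 1-based closed; shift by +1 on the way in, -1 on the way out.
.iv_to_irl <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(IRanges::IRangesList())
  S4Vectors::split(IRanges::IRanges(start = x$start + 1, end = x$end),
                   factor(x$seqid, levels = sort(unique(x$seqid))))
}

.irl_to_iv <- function(irl) {
  if (length(irl) == 0) return(interval_set())
  n <- S4Vectors::elementNROWS(irl)
  interval_set(seqid = rep(names(irl), n),
               start = unlist(lapply(irl, IRanges::start), use.names = FALSE) - 1,
               end = unlist(lapply(irl, IRanges::end), use.names = FALSE))
}

#' Normalize an interval set
#'
#' Merges overlapping and book-ended (gap 0) intervals per seqid and sorts.
#' Idempotent; the result's total length never exceeds the summed input
#' lengths.
#'
#' @param x an interval set (data.frame with seqid/start/end).
#' @return normalized `interval_set`.
#' @export
iv_union <- function(x) {
  x <- as_interval_set(x)
  if (nrow(x) == 0) return(x)
  .irl_to_iv(IRanges::reduce(.iv_to_irl(x)))
}

#' Complement of an interval set within scaffold bounds
#'
#' @param x an interval set; intervals must lie within `seq_lengths`.
#' @param seq_lengths named numeric vector, seqid -> scaffold length.
#'   Scaffolds absent from `x` contribute their full span.
#' @return `interval_set` covering every base not covered by `x`.
#' @export
iv_complement <- function(x, seq_lengths) {
  x <- iv_union(x)
  stopifnot(!is.null(names(seq_lengths)))
  if (nrow(x) > 0) {
    bad <- !(x$seqid %in% names(seq_lengths))
    if (any(bad)) stop("intervals on seqids missing from seq_lengths: ",
                       paste(unique(x$seqid[bad]), collapse = ", "))
    over <- x$end > seq_lengths[x$seqid]
    if (any(over)) stop("interval exceeds scaffold length on ",
                        paste(unique(x$seqid[over]), collapse = ", "))
  }
  out <- lapply(names(seq_lengths), function(sq) {
    len <- seq_lengths[[sq]]
    xi <- x[x$seqid == sq, , drop = FALSE]
    if (nrow(xi) == 0) return(data.frame(seqid = sq, start = 0, end = len))
    starts <- c(0, xi$end)
    ends <- c(xi$start, len)
    keep <- ends > starts
    if (!any(keep)) return(NULL)
    data.frame(seqid = sq, start = starts[keep], end = ends[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) return(interval_set())
  interval_set(out$seqid, out$start, out$end)
}

#' Intersection of two interval sets
#' @param a,b interval sets.
#' @return normalized `interval_set` of bases covered by both.
#' @export
iv_intersect <- function(a, b) {
  a <- iv_union(a); b <- iv_union(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(interval_set())
  common <- intersect(unique(a$seqid), unique(b$seqid))
  if (length(common) == 0) return(interval_set())
  a <- a[a$seqid %in% common, ]; b <- b[b$seqid %in% common, ]
  ia <- .iv_to_irl(a); ib <- .iv_to_irl(b)
  ib <- ib[names(ia)]
  .irl_to_iv(IRanges::intersect(ia, ib))
}

#' Set difference of two interval sets
#' @param a,b interval sets.
#' @return normalized `interval_set` of bases in `a` but not `b`.
#' @export
iv_setdiff <- function(a, b) {
  a <- iv_union(a); b <- iv_union(b)
  if (nrow(a) == 0) return(a)
  if (nrow(b) == 0) return(a)
  shared <- unique(a$seqid)[unique(a$seqid) %in% unique(b$seqid)]
  only_a <- a[!(a$seqid %in% shared), , drop = FALSE]
  if (length(shared) == 0) return(a)
  ia <- .iv_to_irl(a[a$seqid %in% shared, ])
  ib <- .iv_to_irl(b[b$seqid %in% shared, ])
  ib <- ib[names(ia)]
  res <- .irl_to_iv(IRanges::setdiff(ia, ib))
  out <- rbind(as.data.frame(only_a)[c("seqid", "start", "end")],
               as.data.frame(res)[c("seqid", "start", "end")])
  if (nrow(out) == 0) return(interval_set())
  out <- out[order(out$seqid, out$start), ]
  interval_set(out$seqid, out$start, out$end)
}

#' Total number of bases covered by an interval set
#'
#' For a non-normalized set this is the sum of member lengths (bases covered
#' twice count twice); call [iv_union()] first for a footprint.
#' @param x an interval set.
#' @return numeric scalar.
#' @export
iv_total <- function(x) {
  x <- as_interval_set(x)
  if (nrow(x) == 0) return(0)
  sum(x$end - x$start)
}
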