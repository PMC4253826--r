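#' Partition a long read into solid runs and weak regions
#'
#' Classifies every k-mer start position `0 ... nchar(read) - k` of the
#' read as solid or weak against the short-read index and groups the
#' solid positions into maximal runs.  Weak stretches before the first
#' run and after the last run are the head and tail; weak stretches
#' between runs are inner regions.  All coordinates are 0-based,
#' half-open, over k-mer start positions.
#'
#' @param read a single DNA string (lower case accepted).
#' @param index a [kmer_index].
#' @return an object of class `read_partition` with fields
#'   `read`, `k`, `solid` (logical per k-mer position), `runs`
#'   (data frame with 0-based half-open `start`/`end` over k-mer
#'   positions), `n_kmers`, and logicals `has_head`/`has_tail`.
#'   A read shorter than `k`, or with no solid k-mer, has zero runs.
#' @export
partition_read <- function(read, index) {
  stopifnot(inherits(index, "kmer_index"))
  read <- toupper(as.character(read))[1L]
  k <- index$spec$k
  solid <- cx_classify_read(index$ptr, read)
  n_kmers <- length(solid)
  if (n_kmers > 0L && any(solid)) {
    r <- rle(solid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    runs <- data.frame(start = starts[keep], end = ends[keep])
  } else {
    runs <- data.frame(start = integer(0), end = integer(0))
  }
  has_head <- nrow(runs) > 0L && runs$start[1L] > 0L
  # tail exists iff the last solid k-mer does not end at the read's last base
  has_tail <- nrow(runs) > 0L && runs$end[nrow(runs)] < n_kmers
  structure(
    list(read = read, k = k, solid = solid, runs = runs,
         n_kmers = n_kmers, has_head = has_head, has_tail = has_tail),
    class = "read_partition"
  )
}

#' @export
print.read_partition <- function(x, ...) {
  cat(sprintf(
    "read partition: %d bases, k = %d, %d solid of %d k-mer positions, %d run(s)\n",
    nchar(x$read), x$k, sum(x$solid), x$n_kmers, nrow(x$runs)))
  if (nrow(x$runs) > 0L)
    cat(sprintf("  head: %s, inner regions: %d, tail: %s\n",
                x$has_head, max(nrow(x$runs) - 1L, 0L), x$has_tail))
  invisible(x)
}

#' Per-base solidity of a partitioned read
#'
#' Base `i` (0-based) is solid iff it is covered by at least one solid
#' k-mer, i.e. some solid k-mer start `p` satisfies `p <= i < p + k`.
#' This is the classification used for the upper/lower case encoding of
#' corrected reads.
#'
#' @param partition a [read_partition()].
#' @return logical vector of length `nchar(read)`.
#' @export
solid_positions <- function(partition) {
  stopifnot(inherits(partition, "read_partition"))
  n <- nchar(partition$read)
  out <- logical(n)
  k <- partition$k
  if (nrow(partition$runs) > 0L) {
    for (i in seq_len(nrow(partition$runs))) {
      a <- partition$runs$start[i]      # first covered base (0-based)
      b <- partition$runs$end[i] - 1L + k  # one past last covered base
      out[(a + 1L):b] <- TRUE
    }
  }
  out
}
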