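#' k-mer specification for the de Bruijn graph
#'
#' Bundles the parameters that define the short-read de Bruijn graph:
#' the k-mer length, the occurrence threshold below which a k-mer is
#' considered weak (a likely short-read sequencing error), and whether
#' solidity additionally requires at least one incoming and one outgoing
#' graph arc.  `k` must be odd so that no k-mer equals its own reverse
#' complement.
#'
#' @param k odd integer k-mer length, between 3 and 31.
#' @param solid_threshold minimum occurrence count for a solid k-mer
#'   (at least 1).
#' @param require_arcs logical; if `TRUE` (default) a solid k-mer must
#'   also have at least one incoming and one outgoing arc whose
#'   neighbouring k-mer passes the count threshold.  This refinement
#'   rejects isolated spurious k-mers.
#' @return an object of class `kmer_spec`.
#' @examples
#' kmer_spec(19, 3)
#' @export
kmer_spec <- function(k = 19L, solid_threshold = 3L, require_arcs = TRUE) {
  k <- as.integer(k)
  solid_threshold <- as.integer(solid_threshold)
  if (length(k) != 1L || is.na(k) || k < 3L || k > 31L || k %% 2L == 0L)
    stop("`k` must be a single odd integer between 3 and 31", call. = FALSE)
  if (length(solid_threshold) != 1L || is.na(solid_threshold) ||
      solid_threshold < 1L)
    stop("`solid_threshold` must be a single integer >= 1", call. = FALSE)
  if (!is.logical(require_arcs) || length(require_arcs) != 1L ||
      is.na(require_arcs))
    stop("`require_arcs` must be TRUE or FALSE", call. = FALSE)
  structure(
    list(k = k, solid_threshold = solid_threshold,
         require_arcs = require_arcs),
    class = "kmer_spec"
  )
}

#' @export
print.kmer_spec <- function(x, ...) {
  cat(sprintf("k-mer spec: k = %d, solid threshold = %d, require arcs = %s\n",
              x$k, x$solid_threshold, x$require_arcs))
  invisible(x)
}

#' Canonical form of k-mers
#'
#' The canonical k-mer is the lexicographically smaller of a k-mer and its
#' reverse complement, so that both strands of a sequence share one graph
#' node.  Input must be over `A,C,G,T` with odd length (lower case
#' accepted and normalised).
#'
#' @param x character vector of k-mers (odd length, ACGT).
#' @return character vector of canonical k-mers.
#' @examples
#' canonical_kmer(c("AAA", "TTT"))  # both "AAA"
#' @export
canonical_kmer <- function(x) {
  cx_canonical(toupper(as.character(x)))
}

#' Count canonical k-mers in a short-read set
#'
#' Counts every k-length window of the reads under its canonical form.
#' Windows containing `N` (or any non-ACGT character) are skipped; reads
#' shorter than `k` contribute nothing.  The resulting index holds the
#' counts and the solidity rules of `spec`, and is the in-memory
#' de Bruijn graph: nodes are solid k-mers, arcs are (k-1)-base overlaps
#' queried on demand.
#'
#' @param reads character vector of short reads (or anything coercible
#'   via `as.character`, e.g. a `DNAStringSet`).
#' @param spec a [kmer_spec()].
#' @return an object of class `kmer_index`.
#' @examples
#' idx <- count_kmers(c("ACGT"), kmer_spec(3, 1, require_arcs = FALSE))
#' as.data.frame(idx)  # ACG counted twice (CGT canonicalises to ACG)
#' @export
count_kmers <- function(reads, spec = kmer_spec()) {
  stopifnot(inherits(spec, "kmer_spec"))
  reads <- toupper(as.character(reads))
  ptr <- cx_build_index(reads, spec$k, spec$solid_threshold,
                        spec$require_arcs)
  structure(list(spec = spec, ptr = ptr), class = "kmer_index")
}

#' Rebuild a k-mer index from explicit counts
#'
#' Mainly for test fixtures and for reloading a saved index: takes k-mers
#' (canonicalised on entry, counts of a k-mer and its reverse complement
#' are pooled) with positive counts.
#'
#' @param kmers character vector of k-mers.
#' @param counts integer vector of positive counts.
#' @param spec a [kmer_spec()].
#' @return a `kmer_index`.
#' @export
kmer_index <- function(kmers, counts, spec = kmer_spec()) {
  stopifnot(inherits(spec, "kmer_spec"))
  ptr <- cx_index_from_counts(toupper(as.character(kmers)),
                              as.integer(counts),
                              spec$k, spec$solid_threshold,
                              spec$require_arcs)
  structure(list(spec = spec, ptr = ptr), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- cx_index_info(x$ptr)
  cat(sprintf(
    "k-mer index: k = %d, %s distinct canonical k-mers (total count %s)\n",
    info$k, format(info$n_kmers, big.mark = ","),
    format(info$total_count, big.mark = ",")))
  cat(sprintf("  solid threshold %d, require arcs: %s\n",
              info$solid_threshold, info$require_arcs))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.kmer_index <- function(x, ...) {
  cx_index_dump(x$ptr)
}

#' Look up k-mer counts
#'
#' @param index a `kmer_index`.
#' @param kmers character vector of k-mers (either strand).
#' @return integer vector of counts (0 for absent k-mers).
#' @export
kmer_counts <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  cx_kmer_count(index$ptr, toupper(as.character(kmers)))
}

#' Solidity of k-mers
#'
#' A k-mer is solid when its canonical count reaches the index threshold
#' and, if the index requires arcs, at least one of its four single-base
#' right extensions and one of its four left extensions also pass the
#' count threshold.  Extensions are taken in the orientation of the
#' queried k-mer; canonicalisation applies only to count lookups.
#'
#' @param index a `kmer_index`.
#' @param kmers character vector of k-mers.
#' @return logical vector.
#' @export
is_solid <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  cx_is_solid(index$ptr, toupper(as.character(kmers)))
}

#' Graph neighbours of a k-mer
#'
#' Successors are the up-to-four k-mers `substr(x, 2, k)` plus an appended
#' base whose canonical count passes the threshold; predecessors are the
#' symmetric left extensions.  Results come in appended/prepended base
#' order `A < C < G < T`, reported in the orientation that extends the
#' query.
#'
#' @param index a `kmer_index`.
#' @param kmer a single k-mer (need not itself be solid).
#' @return character vector of 0 to 4 k-mers.
#' @export
kmer_successors <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  cx_neighbors(index$ptr, toupper(as.character(kmer))[1L], TRUE)
}

#' @rdname kmer_successors
#' @export
kmer_predecessors <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  cx_neighbors(index$ptr, toupper(as.character(kmer))[1L], FALSE)
}

#' Save / load a k-mer index as a flat text table
#'
#' One `kmer<TAB>count` line per canonical k-mer, sorted lexicographically.
#' The solidity parameters are not stored; supply them again on load.
#'
#' @param index a `kmer_index`.
#' @param path file path.
#' @return `write_kmer_index` returns `path` invisibly; `read_kmer_index`
#'   returns a `kmer_index`.
#' @export
write_kmer_index <- function(index, path) {
  stopifnot(inherits(index, "kmer_index"))
  tab <- as.data.frame(index)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_index
#' @param spec a [kmer_spec()] for the reloaded index.
#' @export
read_kmer_index <- function(path, spec = kmer_spec()) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("kmer", "count"),
                           colClasses = c("character", "integer"))
  kmer_index(tab$kmer, tab$count, spec)
}
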