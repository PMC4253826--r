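#' Path-search parameters
#'
#' Tuning knobs of the de Bruijn graph path searches.  The defaults are
#' the values that work well for bacterial-scale data with `k = 19`:
#' maximum error rate 0.4, branching limit 200, five target k-mers per
#' source.
#'
#' @param max_error_rate fraction in (0, 1]: a bridging path may differ
#'   from the read region by at most `ceiling(max_error_rate * region
#'   length)` edits (the region includes both anchor k-mers).
#' @param branching_limit positive integer: how many non-first branch
#'   alternatives the depth-first search may take before the search of a
#'   region is abandoned.
#' @param target_count positive integer: number of downstream solid
#'   k-mers tried as targets for each source k-mer.
#' @param max_region_span positive integer: maximum base distance, in the
#'   read, between the start of the source k-mer and the end of the
#'   target k-mer; larger spans are skipped.
#' @return an object of class `search_params`.
#' @export
search_params <- function(max_error_rate = 0.4, branching_limit = 200L,
                          target_count = 5L, max_region_span = 500L) {
  branching_limit <- as.integer(branching_limit)
  target_count <- as.integer(target_count)
  max_region_span <- as.integer(max_region_span)
  if (!is.numeric(max_error_rate) || length(max_error_rate) != 1L ||
      is.na(max_error_rate) || max_error_rate <= 0 || max_error_rate > 1)
    stop("`max_error_rate` must be in (0, 1]", call. = FALSE)
  if (is.na(branching_limit) || branching_limit < 1L)
    stop("`branching_limit` must be >= 1", call. = FALSE)
  if (is.na(target_count) || target_count < 1L)
    stop("`target_count` must be >= 1", call. = FALSE)
  if (is.na(max_region_span) || max_region_span < 1L)
    stop("`max_region_span` must be >= 1", call. = FALSE)
  structure(
    list(max_error_rate = max_error_rate,
         branching_limit = branching_limit,
         target_count = target_count,
         max_region_span = max_region_span),
    class = "search_params"
  )
}

#' @export
print.search_params <- function(x, ...) {
  cat(sprintf(
    "search params: max error rate %.3g, branching limit %d, targets %d, max span %d\n",
    x$max_error_rate, x$branching_limit, x$target_count, x$max_region_span))
  invisible(x)
}

#' Levenshtein edit distance
#'
#' Unit-cost edit distance (substitution, insertion, deletion all cost 1).
#'
#' @param a,b character strings.
#' @return non-negative integer.
#' @examples
#' edit_distance("ACGT", "AGT")  # 1
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b)[1L, 1L])
}

#' Bridge search: best de Bruijn path between two solid anchors
#'
#' Depth-first search of graph paths from `source` to `target`, scoring
#' each extension node-wise with an incremental edit-distance row against
#' `region` (which must begin with the source k-mer and end with the
#' target k-mer).  A branch is abandoned as soon as no extension can stay
#' within the error budget `E = ceiling(max_error_rate * nchar(region))`;
#' path length is capped at `nchar(region) + E`.  The whole search
#' returns `ABORTED` once the number of explored branch alternatives
#' exceeds the branching limit, discarding any candidate found.
#'
#' @param index a [kmer_index].
#' @param source,target k-mer strings in the read's orientation; `source`
#'   must be solid.
#' @param region the read substring spanning source k-mer start through
#'   target k-mer end (both anchors included).
#' @param params a [search_params()].
#' @return a list with `status` (`"FOUND"`, `"NO_PATH"` or `"ABORTED"`),
#'   and for `FOUND` the spelled `path_seq` (begins with `source`, ends
#'   with `target`) and its `edit_dist` to the region; plus the number of
#'   `branches` taken and the `error_budget`.
#' @export
bridge_search <- function(index, source, target, region, params = search_params()) {
  stopifnot(inherits(index, "kmer_index"), inherits(params, "search_params"))
  res <- cx_bridge_search(index$ptr, toupper(source), toupper(target),
                          toupper(region), params$max_error_rate,
                          params$branching_limit)
  res
}

#' Extension search: correct a read end from a single anchor
#'
#' For a tail, grows graph paths from `anchor` (the last solid k-mer),
#' scoring node-wise against `segment` (the read from the anchor to its
#' end); a branch is abandoned when its minimal edit distance outgrows
#' `max_error_rate` times the path length (a linear drop-off).  Among all
#' admissible paths the longest (ties: smallest distance) is kept and
#' then trimmed with [best_prefix_alignment()] to the prefix with the
#' best alignment score.  A head is handled symmetrically by
#' reverse-complementing anchor and segment, searching as a tail, and
#' reverse-complementing the result; for `direction = "head"` the
#' segment must therefore *end* with the anchor, and the returned
#' sequences also end with it.
#'
#' @param index a [kmer_index].
#' @param anchor solid k-mer bordering the weak end.
#' @param segment read substring including the anchor (first k bases for
#'   a tail, last k bases for a head).
#' @param direction `"tail"` or `"head"`.
#' @param params a [search_params()].
#' @return a list with `status`, and for `FOUND`: `path_seq` (untrimmed),
#'   `trimmed_seq` (prefix of the path after score trimming; for heads a
#'   suffix in original orientation), `score` (alignment score of the
#'   trimmed sequence against the matched part of the segment) and
#'   `seg_used` (number of segment bases, anchor included, covered by the
#'   trimmed correction).
#' @export
extension_search <- function(index, anchor, segment,
                             direction = c("tail", "head"),
                             params = search_params()) {
  stopifnot(inherits(index, "kmer_index"), inherits(params, "search_params"))
  direction <- match.arg(direction)
  anchor <- toupper(anchor)
  segment <- toupper(segment)
  k <- index$spec$k
  if (direction == "tail") {
    if (substr(segment, 1L, k) != anchor)
      stop("tail segment must begin with the anchor k-mer", call. = FALSE)
    a <- anchor; s <- segment
  } else {
    if (substr(segment, nchar(segment) - k + 1L, nchar(segment)) != anchor)
      stop("head segment must end with the anchor k-mer", call. = FALSE)
    a <- revcomp(anchor); s <- revcomp(segment)
  }
  res <- cx_extension_search(index$ptr, a, s, params$max_error_rate,
                             params$branching_limit)
  if (res$status != "FOUND")
    return(list(status = res$status, path_seq = NULL, trimmed_seq = NULL,
                score = NA_integer_, seg_used = NA_integer_,
                branches = res$branches))
  bp <- cx_best_prefix_alignment(res$path_seq, s, k)
  trimmed <- substr(res$path_seq, 1L, bp$length)
  path_seq <- res$path_seq
  if (direction == "head") {
    trimmed <- revcomp(trimmed)
    path_seq <- revcomp(path_seq)
  }
  list(status = "FOUND", path_seq = path_seq, trimmed_seq = trimmed,
       score = bp$score, seg_used = bp$seg_length, branches = res$branches)
}

#' Best-scoring prefix of a path against a segment
#'
#' Over all prefixes of `path_seq` (of length at least `min_len`, by
#' default the full anchor must stay), finds the prefix maximising the
#' best global-alignment score against any prefix of `segment`, scoring
#' match +1, mismatch -1, gap -1.  Ties are broken toward the longer
#' path prefix, then the longer segment prefix.
#'
#' @param path_seq,segment strings beginning at the same anchor.
#' @param min_len minimum prefix length considered (default: full
#'   `path_seq` may not be shortened below 1; searches pass the k-mer
#'   length so the anchor is never cut).
#' @return list with `length` (chosen prefix length of `path_seq`),
#'   `seg_length` (matched prefix length of `segment`) and `score`.
#' @export
best_prefix_alignment <- function(path_seq, segment, min_len = 1L) {
  cx_best_prefix_alignment(toupper(path_seq), toupper(segment),
                           as.integer(min_len))
}
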