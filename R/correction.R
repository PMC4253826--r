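`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate source/target anchor pairs for bridging
#'
#' Loops over the solid k-mer positions of the read in order; each
#' position is a source, paired with its next `target_count` solid
#' positions.  A pair is actioned as:
#' \describe{
#'   \item{`SKIP_SAME_RUN`}{both anchors in one solid run - the spanned
#'     sequence is assumed correct;}
#'   \item{`SKIP_OVERLAP`}{anchors in different runs but overlapping in
#'     the read (`q - p < k`), as around tandem repeats or false solid
#'     k-mers;}
#'   \item{`SKIP_TOO_FAR`}{spanned bases `q + k - p` exceed
#'     `max_region_span`;}
#'   \item{`SEARCH`}{a bridge search is attempted.}
#' }
#'
#' @param partition a [read_partition()] with at least one run.
#' @param params a [search_params()].
#' @return data frame with 0-based k-mer positions `source`, `target` and
#'   character `action`, in read order.
#' @export
select_pairs <- function(partition, params = search_params()) {
  stopifnot(inherits(partition, "read_partition"),
            inherits(params, "search_params"))
  if (nrow(partition$runs) == 0L)
    stop("partition has no solid run", call. = FALSE)
  P <- which(partition$solid) - 1L
  run_id <- rep.int(seq_len(nrow(partition$runs)),
                    partition$runs$end - partition$runs$start)
  nP <- length(P)
  t <- params$target_count
  k <- partition$k
  i <- rep(seq_len(nP), each = t)
  j <- i + rep.int(seq_len(t), nP)
  keep <- j <= nP
  i <- i[keep]; j <- j[keep]
  p <- P[i]; q <- P[j]
  action <- ifelse(run_id[i] == run_id[j], "SKIP_SAME_RUN",
            ifelse(q - p < k, "SKIP_OVERLAP",
            ifelse(q + k - p > params$max_region_span, "SKIP_TOO_FAR",
                   "SEARCH")))
  data.frame(source = p, target = q, action = action)
}

#' Build the per-read path graph
#'
#' Nodes are the solid k-mer occurrence positions of the read.  Arcs:
#' \itemize{
#'   \item weight-0 arcs between consecutive positions inside a solid
#'     run, carrying the original bases;
#'   \item bridge arcs for every successful bridge search over a
#'     `SEARCH` pair, weighted by the edit distance and carrying the path
#'     sequence;
#'   \item a dummy arc from any run-end source whose trials all failed to
#'     the next solid position, weighted by the spanned region length and
#'     carrying the original (possibly partially corrected) bases.  For
#'     such regions a one-sided fallback is attempted: extension searches
#'     inward from both flanks correct a prefix and a suffix of the
#'     region, and a successful fallback lowers the dummy weight by the
#'     number of weak bases covered (floored at 1).
#' }
#' The dummy arcs guarantee a directed path from the first to the last
#' solid position.
#'
#' @param read the read sequence the partition was computed from.
#' @param partition its [read_partition()] (at least one run).
#' @param index a [kmer_index].
#' @param params a [search_params()].
#' @return an object of class `path_graph`: list with `nodes` (0-based
#'   solid positions) and `arcs` (data frame `src`, `dst`, `weight`,
#'   `type`, `replacement`).
#' @export
build_path_graph <- function(read, partition, index, params = search_params()) {
  stopifnot(inherits(partition, "read_partition"))
  read <- toupper(as.character(read)[1L])
  k <- partition$k
  runs <- partition$runs
  P <- which(partition$solid) - 1L

  src <- integer(0); dst <- integer(0); wt <- integer(0)
  type <- character(0); rep_seq <- character(0)

  # intra-run weight-0 arcs between consecutive solid positions
  inrun <- P[-length(P)] + 1L == P[-1L]
  if (length(P) > 1L && any(inrun)) {
    a <- P[-length(P)][inrun]
    src <- c(src, a); dst <- c(dst, a + 1L)
    wt <- c(wt, rep.int(0L, length(a)))
    type <- c(type, rep.int("run", length(a)))
    rep_seq <- c(rep_seq, substring(read, a + 1L, a + 1L + k))
  }

  pairs <- select_pairs(partition, params)
  found_from <- integer(0)
  for (m in which(pairs$action == "SEARCH")) {
    p <- pairs$source[m]; q <- pairs$target[m]
    region <- substr(read, p + 1L, q + k)
    br <- bridge_search(index, substr(read, p + 1L, p + k),
                        substr(read, q + 1L, q + k), region, params)
    if (br$status == "FOUND") {
      src <- c(src, p); dst <- c(dst, q)
      wt <- c(wt, br$edit_dist)
      type <- c(type, "bridge")
      rep_seq <- c(rep_seq, br$path_seq)
      found_from <- c(found_from, p)
    }
  }

  # dummy arcs from run ends whose bridge trials all failed
  if (nrow(runs) > 1L) {
    for (r in seq_len(nrow(runs) - 1L)) {
      p <- runs$end[r] - 1L
      if (p %in% found_from) next
      q0 <- runs$start[r + 1L]
      region <- substr(read, p + 1L, q0 + k)
      L <- nchar(region)
      fb <- one_sided_fallback(read, p, q0, region, index, params)
      src <- c(src, p); dst <- c(dst, q0)
      wt <- c(wt, max(1L, L - fb$gain))
      type <- c(type, if (fb$gain > 0L) "partial" else "dummy")
      rep_seq <- c(rep_seq, fb$replacement)
    }
  }

  arcs <- data.frame(src = src, dst = dst, weight = wt, type = type,
                     replacement = rep_seq)
  arcs <- arcs[order(arcs$src, arcs$dst, arcs$weight), , drop = FALSE]
  rownames(arcs) <- NULL
  structure(list(nodes = P, arcs = arcs, k = k, read = read),
            class = "path_graph")
}

# Extension searches inward from both flanks of an unbridged region.
# A flank correction is used only when it leaves the opposite anchor
# untouched (seg_used <= L - k) and the two corrections do not overlap.
one_sided_fallback <- function(read, p, q0, region, index, params) {
  k <- k_of(index)
  L <- nchar(region)
  jL <- 0L; tL <- ""
  jR <- 0L; tR <- ""
  left <- extension_search(index, substr(read, p + 1L, p + k), region,
                           "tail", params)
  if (left$status == "FOUND" && left$seg_used > k &&
      left$seg_used <= L - k) {
    jL <- left$seg_used; tL <- left$trimmed_seq
  }
  right <- extension_search(index, substr(read, q0 + 1L, q0 + k), region,
                            "head", params)
  if (right$status == "FOUND" && right$seg_used > k &&
      right$seg_used <= L - k) {
    jR <- right$seg_used; tR <- right$trimmed_seq
  }
  if (jL + jR > L) { jR <- 0L; tR <- "" }  # overlapping: keep left only
  if (jL == 0L && jR == 0L)
    return(list(replacement = region, gain = 0L))
  mid <- substr(region, jL + 1L, L - jR)
  gain <- max(0L, jL - k) + max(0L, jR - k)
  list(replacement = paste0(tL, mid, tR), gain = gain)
}

k_of <- function(index) index$spec$k

#' @export
print.path_graph <- function(x, ...) {
  tab <- table(x$arcs$type)
  cat(sprintf("path graph: %d nodes, %d arcs (%s)\n", length(x$nodes),
              nrow(x$arcs),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Shortest correction through the path graph
#'
#' Minimum-total-weight path from the first to the last solid k-mer
#' position.  All arcs point forward in read coordinates, so Dijkstra's
#' relaxation is performed in position order; ties are broken by fewer
#' arcs, then by the earliest-position arc ordering.
#'
#' @param pg a [build_path_graph()] result.
#' @return the chosen arcs, in order, as a data frame (zero rows when the
#'   graph has a single node).
#' @export
shortest_correction <- function(pg) {
  stopifnot(inherits(pg, "path_graph"))
  nodes <- pg$nodes
  nn <- length(nodes)
  if (nn <= 1L) return(pg$arcs[0L, , drop = FALSE])
  idx <- match(pg$arcs$src, nodes)
  jdx <- match(pg$arcs$dst, nodes)
  if (anyNA(idx) || anyNA(jdx))
    stop("arc endpoint not among path-graph nodes", call. = FALSE)
  dist <- rep(Inf, nn); narc <- rep(Inf, nn); parent <- rep(NA_integer_, nn)
  dist[1L] <- 0; narc[1L] <- 0
  ord <- order(idx, jdx)
  for (a in ord) {
    u <- idx[a]; v <- jdx[a]
    if (!is.finite(dist[u])) next
    dcand <- dist[u] + pg$arcs$weight[a]
    ncand <- narc[u] + 1
    if (dcand < dist[v] || (dcand == dist[v] && ncand < narc[v])) {
      dist[v] <- dcand; narc[v] <- ncand; parent[v] <- a
    }
  }
  if (!is.finite(dist[nn]))
    stop("path graph invariant violated: no path to the last solid k-mer",
         call. = FALSE)
  sel <- integer(0)
  v <- nn
  while (v != 1L) {
    a <- parent[v]
    sel <- c(a, sel)
    v <- idx[a]
  }
  out <- pg$arcs[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

corrected_read <- function(name, seq, skipped) {
  structure(list(name = name %||% NA_character_, seq = seq,
                 skipped = skipped),
            class = "corrected_read")
}

#' @export
print.corrected_read <- function(x, ...) {
  cat(sprintf("corrected read%s: %d bases, %d solid%s\n",
              if (is.na(x$name)) "" else paste0(" ", x$name),
              nchar(x$seq),
              sum(strsplit(x$seq, "")[[1]] %in% c("A", "C", "G", "T")),
              if (x$skipped) " (skipped: no solid k-mer)" else ""))
  invisible(x)
}

#' @export
as.character.corrected_read <- function(x, ...) {
  stats::setNames(x$seq, if (is.na(x$name)) NULL else x$name)
}

# One directional pass: partition, head/tail extension, inner bridging
# via the path graph, splice.  NULL when the read has no solid k-mer.
correct_pass <- function(seq, index, params) {
  part <- partition_read(seq, index)
  if (nrow(part$runs) == 0L) return(NULL)
  k <- part$k
  n <- nchar(seq)
  P <- which(part$solid) - 1L
  pfirst <- P[1L]; plast <- P[length(P)]

  head_part <- substr(seq, 1L, pfirst + k)
  if (pfirst > 0L) {
    ext <- extension_search(index, substr(seq, pfirst + 1L, pfirst + k),
                            head_part, "head", params)
    if (ext$status == "FOUND")
      head_part <- paste0(substr(seq, 1L, pfirst + k - ext$seg_used),
                          ext$trimmed_seq)
  }

  if (length(P) > 1L) {
    pg <- build_path_graph(seq, part, index, params)
    sel <- shortest_correction(pg)
    reps <- sel$replacement
    mid <- paste0(reps[1L],
                  paste(substring(reps[-1L], k + 1L), collapse = ""))
  } else {
    mid <- substr(seq, pfirst + 1L, pfirst + k)
  }

  if (plast + k < n) {
    segment <- substr(seq, plast + 1L, n)
    ext <- extension_search(index, substr(seq, plast + 1L, plast + k),
                            segment, "tail", params)
    tail_part <- if (ext$status == "FOUND")
      paste0(ext$trimmed_seq, substr(seq, plast + ext$seg_used + 1L, n))
    else segment
  } else {
    tail_part <- substr(seq, plast + 1L, plast + k)
  }

  paste0(head_part, substring(mid, k + 1L), substring(tail_part, k + 1L))
}

#' Correct one long read
#'
#' Runs two directional passes over the read.  Each pass partitions the
#' (current) sequence into solid runs and weak regions, corrects the head
#' and tail by extension searches, bridges the inner weak regions through
#' the de Bruijn graph, and splices the shortest-path selection of
#' corrections into the read.  The second pass operates on the reverse
#' complement of the first pass's output, so path searches start from the
#' opposite ends, then the result is flipped back.  The final sequence is
#' case-encoded: bases covered by at least one solid k-mer are upper
#' case, all others lower case.  A read without any solid k-mer is
#' returned unchanged, entirely lower case, with `skipped = TRUE`.
#'
#' @param read a single DNA string.
#' @param index a [kmer_index] built from the short reads.
#' @param params a [search_params()].
#' @param name optional read identifier carried to the output.
#' @return an object of class `corrected_read` with fields `name`, `seq`
#'   (case-encoded) and `skipped`.
#' @export
correct_read <- function(read, index, params = search_params(), name = NULL) {
  stopifnot(inherits(index, "kmer_index"), inherits(params, "search_params"))
  orig <- toupper(as.character(read)[1L])
  p1 <- correct_pass(orig, index, params)
  if (is.null(p1))
    return(corrected_read(name, tolower(orig), skipped = TRUE))
  p2 <- correct_pass(revcomp(p1), index, params)
  final <- if (is.null(p2)) p1 else revcomp(p2)
  part <- partition_read(final, index)
  cover <- solid_positions(part)
  chars <- strsplit(final, "")[[1L]]
  chars[!cover] <- tolower(chars[!cover])
  corrected_read(name, paste(chars, collapse = ""), skipped = FALSE)
}

#' Correct a set of long reads
#'
#' @param reads named character vector (or `DNAStringSet`) of long reads.
#' @param index a [kmer_index].
#' @param params a [search_params()].
#' @return a list of [correct_read()] results, class `corrected_read_set`.
#' @export
correct_reads <- function(reads, index, params = search_params()) {
  seqs <- stats::setNames(as.character(reads), names(reads))
  nms <- names(seqs) %||% paste0("read_", seq_along(seqs))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs))
    out[[i]] <- correct_read(seqs[[i]], index, params, name = nms[[i]])
  names(out) <- nms
  class(out) <- "corrected_read_set"
  out
}

#' @export
print.corrected_read_set <- function(x, ...) {
  nsk <- sum(vapply(x, function(r) r$skipped, logical(1)))
  cat(sprintf("corrected read set: %d reads (%d skipped)\n", length(x), nsk))
  invisible(x)
}

#' @export
as.character.corrected_read_set <- function(x, ...) {
  vapply(unclass(x), function(r) r$seq, character(1))
}
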