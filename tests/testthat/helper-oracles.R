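# Independent oracles and small fixture builders.  Everything here is
# deliberately naive (double loops, exhaustive enumeration) so it cannot
# share a failure mode with the package's incremental implementations.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

oracle_canonical <- function(x) {
  pmin(x, oracle_revcomp(x))
}

# direct double-loop canonical k-mer counter (N windows skipped)
oracle_count <- function(reads, k) {
  tab <- new.env(parent = emptyenv())
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(r, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      cw <- oracle_canonical(w)
      tab[[cw]] <- (if (is.null(tab[[cw]])) 0L else tab[[cw]]) + 1L
    }
  }
  keys <- sort(ls(tab))
  stats::setNames(vapply(keys, function(kk) tab[[kk]], 0L), keys)
}

oracle_is_solid <- function(counts, kmer, threshold, require_arcs) {
  cnt <- function(x) {
    v <- counts[oracle_canonical(x)]
    ifelse(is.na(v), 0L, v)
  }
  if (cnt(kmer) < threshold) return(FALSE)
  if (!require_arcs) return(TRUE)
  k <- nchar(kmer)
  rights <- paste0(substr(kmer, 2L, k), c("A", "C", "G", "T"))
  lefts <- paste0(c("A", "C", "G", "T"), substr(kmer, 1L, k - 1L))
  any(cnt(rights) >= threshold) && any(cnt(lefts) >= threshold)
}

# exhaustive enumeration of DBG paths source -> target up to maxlen bases,
# capped at `cap` completed paths (NULL return when the cap is hit)
oracle_enum_paths <- function(index, source, target, maxlen, cap = 500L) {
  paths <- character(0)
  hit_cap <- FALSE
  recurse <- function(path, node) {
    if (hit_cap) return(invisible(NULL))
    if (node == target && nchar(path) > nchar(source)) {
      paths <<- c(paths, path)
      if (length(paths) >= cap) hit_cap <<- TRUE
    }
    if (nchar(path) >= maxlen) return(invisible(NULL))
    for (succ in kmer_successors(index, node)) {
      recurse(paste0(path, substr(succ, nchar(succ), nchar(succ))), succ)
    }
    invisible(NULL)
  }
  if (source == target) paths <- c(paths, source)
  recurse(source, source)
  if (hit_cap) NULL else paths
}

# oracle for bridge_search: score every enumerated path with full-DP
# edit distance; NA when no path fits the budget
oracle_best_bridge <- function(index, source, target, region, rate,
                               cap = 500L) {
  E <- ceiling(rate * nchar(region))
  paths <- oracle_enum_paths(index, source, target, nchar(region) + E, cap)
  if (is.null(paths)) return(NULL)  # too many paths for the oracle
  if (length(paths) == 0L) return(NA_integer_)
  d <- as.integer(utils::adist(paths, region))
  d <- d[d <= E]
  if (length(d) == 0L) NA_integer_ else min(d)
}

# brute-force shortest path over a path_graph by enumerating all paths
oracle_shortest_weight <- function(pg) {
  nodes <- pg$nodes
  arcs <- pg$arcs
  best <- Inf
  recurse <- function(node, w) {
    if (node == nodes[length(nodes)]) {
      best <<- min(best, w)
      return(invisible(NULL))
    }
    out <- which(arcs$src == node)
    for (a in out) recurse(arcs$dst[a], w + arcs$weight[a])
    invisible(NULL)
  }
  recurse(nodes[1L], 0)
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# index over a single sequence with all k-mers kept (threshold 1)
seq_index <- function(seqs, k, threshold = 1L, require_arcs = FALSE) {
  count_kmers(seqs, kmer_spec(k, threshold, require_arcs))
}

# plant point errors into a genome substring at fixed interior offsets
plant_errors <- function(seq, offsets, ops, bases) {
  pieces <- strsplit(seq, "")[[1L]]
  for (i in seq_along(offsets)) {
    p <- offsets[i]
    if (ops[i] == "S") pieces[p] <- bases[i]
    else if (ops[i] == "D") pieces[p] <- ""
    else pieces[p] <- paste0(bases[i], pieces[p])
  }
  paste(pieces, collapse = "")
}

# plain-R Needleman-Wunsch score matrix (match +1, mismatch -1, gap -1);
# entry [a+1, b+1] is the global score of p[1..a] vs s[1..b]
nw_matrix <- function(p, s) {
  a <- nchar(p); b <- nchar(s)
  S <- matrix(0L, a + 1L, b + 1L)
  S[, 1L] <- -(0:a); S[1L, ] <- -(0:b)
  pc <- strsplit(p, "")[[1L]]; sc <- strsplit(s, "")[[1L]]
  for (i in seq_len(a)) for (j in seq_len(b)) {
    S[i + 1L, j + 1L] <- max(S[i, j] + (if (pc[i] == sc[j]) 1L else -1L),
                             S[i, j + 1L] - 1L, S[i + 1L, j] - 1L)
  }
  S
}

nw_score <- function(p, s) nw_matrix(p, s)[nchar(p) + 1L, nchar(s) + 1L]
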