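test_that("edit_distance is the unit-cost Levenshtein distance", {
  expect_equal(edit_distance("", "ACG"), 3L)
  expect_equal(edit_distance("ACGTACGT", "ACGTACGT"), 0L)
  expect_equal(edit_distance("ACGT", "AGT"), 1L)
  set.seed(31)
  for (i in 1:10) {
    a <- random_dna(sample(0:12, 1)); b <- random_dna(sample(0:12, 1))
    c <- random_dna(sample(0:12, 1))
    expect_equal(edit_distance(a, b), edit_distance(b, a))
    expect_lte(edit_distance(a, c),
               edit_distance(a, b) + edit_distance(b, c))
  }
})

test_that("bridge search recovers the unique path exactly", {
  # fixed sequence with no repeated 6-mer on either strand: unique path
  S <- "TATGCGTTTATCAATGCGCCCAGGGAACGTGTGTGATGTAAAGTCCATTCGAGTCTTCCC"
  k <- 7L
  idx <- seq_index(S, k)
  src <- substr(S, 1, k)
  tgt <- substr(S, nchar(S) - k + 1, nchar(S))
  res <- bridge_search(idx, src, tgt, S)
  expect_equal(res$status, "FOUND")
  expect_equal(res$path_seq, S)
  expect_equal(res$edit_dist, 0L)
})

test_that("bridge search on a diamond graph matches the enumeration oracle", {
  # pre/post chosen so all 4-mers are distinct across both strands:
  # the graph is a clean diamond with a single interior divergence
  k <- 5L
  pre <- "GGGACCCGAGTG"; post <- "CAAGATAGGATG"
  v1 <- paste0(pre, "A", post)
  v2 <- paste0(pre, "G", post)
  idx <- count_kmers(c(v1, v1, v2, v2), kmer_spec(k, 2, require_arcs = FALSE))
  src <- substr(v1, 1, k)
  tgt <- substr(v1, nchar(v1) - k + 1, nchar(v1))
  params <- search_params()

  res <- bridge_search(idx, src, tgt, v1, params)
  expect_equal(res$status, "FOUND")
  expect_equal(res$path_seq, v1)
  expect_equal(res$edit_dist, 0L)
  expect_equal(oracle_best_bridge(idx, src, tgt, v1, params$max_error_rate),
               0L)

  # one inserted base in the region: distance 1, same chosen path
  region2 <- paste0(substr(v1, 1, 8), "T", substring(v1, 9))
  res2 <- bridge_search(idx, src, tgt, region2, params)
  expect_equal(res2$status, "FOUND")
  expect_equal(res2$edit_dist, 1L)
  expect_equal(res2$path_seq, v1)
  expect_equal(oracle_best_bridge(idx, src, tgt, region2,
                                  params$max_error_rate), 1L)
})

test_that("the branching limit aborts and discards; raising it never hurts", {
  k <- 5L
  pre <- "TCCAGTCAGG"; mid <- "ACGCAGAGGT"; post <- "TCGCCGAGTA"
  variants <- c(paste0(pre, "A", mid, "A", post),
                paste0(pre, "A", mid, "G", post),
                paste0(pre, "G", mid, "A", post),
                paste0(pre, "G", mid, "G", post))
  idx <- count_kmers(rep(variants, 2), kmer_spec(k, 2, require_arcs = FALSE))
  region <- variants[1]
  src <- substr(region, 1, k)
  tgt <- substr(region, nchar(region) - k + 1, nchar(region))

  tight <- bridge_search(idx, src, tgt, region,
                         search_params(branching_limit = 1))
  expect_equal(tight$status, "ABORTED")
  expect_null(tight$path_seq)

  loose <- bridge_search(idx, src, tgt, region, search_params())
  expect_equal(loose$status, "FOUND")
  expect_equal(loose$edit_dist, 0L)
  expect_equal(loose$path_seq, region)
})

test_that("bridge search equals the exhaustive oracle on random small graphs", {
  set.seed(35)
  params <- search_params()
  checked <- 0L
  for (trial in 1:40) {
    k <- sample(c(3L, 5L), 1)
    g <- random_dna(if (k == 3L) 25L else 45L)
    idx <- seq_index(g, k)
    n <- nchar(g)
    p <- sample(1:(n - 3 * k), 1)
    q <- sample((p + k):(n - k + 1), 1)
    region <- substr(g, p, q + k - 1)
    # sometimes perturb the region with a substitution
    if (trial %% 2 == 0) {
      m <- sample(seq_len(nchar(region)), 1)
      substr(region, m, m) <- sample(c("A", "C", "G", "T"), 1)
    }
    src <- substr(g, p, p + k - 1)
    tgt <- substr(g, q, q + k - 1)
    want <- oracle_best_bridge(idx, src, tgt, region, params$max_error_rate)
    if (is.null(want)) next  # oracle path cap hit
    got <- bridge_search(idx, src, tgt, region, params)
    if (got$status == "ABORTED") next
    checked <- checked + 1L
    if (is.na(want)) {
      expect_equal(got$status, "NO_PATH")
    } else {
      expect_equal(got$status, "FOUND")
      expect_equal(got$edit_dist, want)
      # reported distance is a true full-DP distance and within budget
      expect_equal(edit_distance(got$path_seq, region), got$edit_dist)
      expect_lte(got$edit_dist,
                 ceiling(params$max_error_rate * nchar(region)))
    }
  }
  expect_gte(checked, 20L)
})

test_that("extension search follows the unique path and trims at divergence", {
  set.seed(36)
  k <- 7L
  S <- "ACCTAGAGTCCCATTGAACTAATGTGCCCCAACTCTCGGGCGGTCCCTTA"
  idx <- seq_index(S, k)
  anchor <- substr(S, 1, k)

  exact <- extension_search(idx, anchor, S, "tail")
  expect_equal(exact$status, "FOUND")
  expect_equal(exact$trimmed_seq, S)
  expect_equal(exact$seg_used, nchar(S))

  # segment diverges from the graph after 30 bases
  seg <- paste0(substr(S, 1, 30), random_dna(15))
  div <- extension_search(idx, anchor, seg, "tail")
  expect_equal(div$status, "FOUND")
  expect_gte(nchar(div$trimmed_seq), 30 - k)
  # score must equal the exhaustive prefix-pair oracle on the chosen path
  M <- nw_matrix(div$path_seq, seg)
  expect_equal(div$score, max(M[(k + 1):nrow(M), ]))

  # anchor with no solid successor
  lonely <- kmer_index(anchor, 2L, kmer_spec(k, 1, require_arcs = FALSE))
  expect_equal(extension_search(lonely, anchor, S, "tail")$status,
               "NO_PATH")
})

test_that("head extension is the strand-symmetric image of a tail search", {
  k <- 7L
  S <- "ACCTAGAGTCCCATTGAACTAATGTGCCCCAACTCTCGGGCGGTCCCTTA"
  idx <- seq_index(S, k)
  anchor <- substr(S, nchar(S) - k + 1, nchar(S))
  res <- extension_search(idx, anchor, S, "head")
  expect_equal(res$status, "FOUND")
  expect_equal(res$trimmed_seq, S)
  expect_equal(res$seg_used, nchar(S))
})

test_that("best_prefix_alignment maximises score with ties toward length", {
  seg <- "ACGTACGTAA"
  expect_equal(best_prefix_alignment(seg, seg),
               list(length = nchar(seg), seg_length = nchar(seg),
                    score = nchar(seg)))
  # trailing junk only loses score: trimmed back to the full segment
  noisy <- paste0(seg, "GGGG")
  bp <- best_prefix_alignment(noisy, seg)
  expect_equal(bp$length, nchar(seg))
  expect_equal(bp$score, nchar(seg))
  # a path equal to the anchor alone stays at the anchor
  bp2 <- best_prefix_alignment("ACGTA", seg, min_len = 5L)
  expect_equal(bp2$length, 5L)
  # exhaustive-DP oracle over all prefix pairs on random instances
  set.seed(38)
  for (i in 1:10) {
    p <- random_dna(sample(4:12, 1)); s <- random_dna(sample(4:12, 1))
    bp <- best_prefix_alignment(p, s, min_len = 1L)
    best <- -Inf
    for (a in 1:nchar(p)) for (b in 0:nchar(s)) {
      pa <- substr(p, 1, a); sb <- substr(s, 1, b)
      # global alignment score via needleman-wunsch in plain R
      sc <- nw_score(pa, sb)
      if (sc > best) best <- sc
    }
    expect_equal(bp$score, best)
  }
})
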