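# partition stub: solid/weak pattern is all select_pairs needs
fake_partition <- function(solid, k) {
  r <- rle(solid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  structure(list(read = strrep("A", length(solid) + k - 1), k = k,
                 solid = solid, runs = runs, n_kmers = length(solid),
                 has_head = FALSE, has_tail = FALSE),
            class = "read_partition")
}

test_that("pair selection applies the same-run, overlap and distance rules", {
  k <- 5L
  # one run: every pair skipped as same-run
  p1 <- fake_partition(rep(TRUE, 10), k)
  sp1 <- select_pairs(p1, search_params())
  expect_true(all(sp1$action == "SKIP_SAME_RUN"))
  expect_equal(nrow(sp1), sum(pmin(5L, 9:0)))

  # two runs whose facing k-mers overlap (gap of 1 weak position)
  p2 <- fake_partition(c(rep(TRUE, 3), FALSE, rep(TRUE, 3)), k)
  sp2 <- select_pairs(p2, search_params())
  facing <- sp2$source == 2L & sp2$target == 4L
  expect_true(any(facing))
  expect_equal(unique(sp2$action[facing]), "SKIP_OVERLAP")

  # three runs: brute-force the rules pair by pair
  solid <- c(rep(TRUE, 4), rep(FALSE, 6), rep(TRUE, 3), rep(FALSE, 12),
             rep(TRUE, 5))
  p3 <- fake_partition(solid, k)
  params <- search_params(max_region_span = 20L)
  sp3 <- select_pairs(p3, params)
  P <- which(solid) - 1L
  run_of <- cumsum(c(TRUE, diff(P) > 1L))
  expected <- do.call(rbind, lapply(seq_along(P), function(i) {
    js <- seq(i + 1L, length.out = min(params$target_count,
                                       length(P) - i))
    if (length(js) == 0L) return(NULL)
    data.frame(source = P[i], target = P[js],
               action = vapply(js, function(j) {
                 if (run_of[i] == run_of[j]) "SKIP_SAME_RUN"
                 else if (P[j] - P[i] < k) "SKIP_OVERLAP"
                 else if (P[j] + k - P[i] > params$max_region_span)
                   "SKIP_TOO_FAR"
                 else "SEARCH"
               }, ""))
  }))
  rownames(expected) <- NULL
  expect_equal(sp3, expected)
})

test_that("path graph of a fully solid read is a weight-0 chain", {
  set.seed(41)
  read <- random_dna(60)
  idx <- seq_index(read, 7)
  part <- partition_read(read, idx)
  pg <- build_path_graph(read, part, idx)
  expect_true(all(pg$arcs$weight == 0L))
  expect_true(all(pg$arcs$type == "run"))
  sel <- shortest_correction(pg)
  expect_equal(sum(sel$weight), 0)
  expect_equal(nrow(sel), length(pg$nodes) - 1L)
})

test_that("a bridgeable substitution yields an arc at its edit distance", {
  set.seed(42)
  genome <- random_dna(500)
  k <- 9L
  idx <- seq_index(genome, k)
  read <- substr(genome, 101, 300)
  truth <- read
  substr(read, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                    substr(read, 100, 100))[1]
  part <- partition_read(read, idx)
  pg <- build_path_graph(read, part, idx)
  bridges <- pg$arcs[pg$arcs$type == "bridge", ]
  expect_gte(nrow(bridges), 1L)
  expect_true(any(bridges$weight == 1L))
  sel <- shortest_correction(pg)
  expect_equal(sum(sel$weight), 1)
})

test_that("an unbridgeable region falls back to a dummy arc of full weight", {
  set.seed(43)
  k <- 9L
  genome <- random_dna(400)
  idx <- seq_index(genome, k)
  # a foreign 40-base block interrupts two genomic segments
  foreign <- random_dna(40)
  read <- paste0(substr(genome, 1, 150), foreign, substr(genome, 151, 300))
  part <- partition_read(read, idx)
  pg <- build_path_graph(read, part, idx)
  dummies <- pg$arcs[pg$arcs$type %in% c("dummy", "partial"), ]
  expect_equal(nrow(dummies), 1L)
  if (dummies$type[1] == "dummy") {
    span <- dummies$dst[1] + k - dummies$src[1]
    expect_equal(dummies$weight[1], span)
    expect_equal(dummies$replacement[1],
                 substr(read, dummies$src[1] + 1L, dummies$dst[1] + k))
  }
  # the corrected read keeps the genomic flanks intact
  cr <- correct_read(read, idx)
  expect_false(cr$skipped)
})

test_that("shortest_correction equals brute force on random DAGs", {
  set.seed(44)
  expect_equal(shortest_correction(
    structure(list(nodes = c(0L, 3L, 7L),
                   arcs = data.frame(src = c(0L, 3L), dst = c(3L, 7L),
                                     weight = c(2L, 1L),
                                     type = "bridge",
                                     replacement = c("x", "y"))),
              class = "path_graph"))$weight, c(2L, 1L))
  pg2 <- structure(list(nodes = c(0L, 5L),
                        arcs = data.frame(src = c(0L, 0L), dst = c(5L, 5L),
                                          weight = c(3L, 2L),
                                          type = "bridge",
                                          replacement = c("a", "b"))),
                   class = "path_graph")
  expect_equal(shortest_correction(pg2)$weight, 2L)

  for (trial in 1:30) {
    nn <- sample(3:12, 1)
    nodes <- sort(sample(0:50, nn))
    # chain for connectivity plus random forward arcs
    src <- nodes[-nn]; dst <- nodes[-1L]
    extra <- sample(nn - 1L, sample(seq_len(nn - 1L), 1))
    for (e in extra) {
      cand <- seq(e + 1L, nn)
      j <- cand[sample.int(length(cand), 1)]
      src <- c(src, nodes[e]); dst <- c(dst, nodes[j])
    }
    arcs <- data.frame(src = src, dst = dst,
                       weight = sample(0:9, length(src), replace = TRUE),
                       type = "bridge",
                       replacement = "")
    arcs <- arcs[order(arcs$src, arcs$dst), ]
    pg <- structure(list(nodes = nodes, arcs = arcs), class = "path_graph")
    sel <- shortest_correction(pg)
    expect_equal(sum(sel$weight), oracle_shortest_weight(pg))
    # the selection is a connected first-to-last path
    expect_equal(sel$src[1], nodes[1])
    expect_equal(sel$dst[nrow(sel)], nodes[nn])
    if (nrow(sel) > 1L)
      expect_equal(sel$src[-1L], sel$dst[-nrow(sel)])
  }
})

test_that("correcting an exact genomic read is a fixed point", {
  set.seed(45)
  genome <- random_dna(600)
  idx <- seq_index(genome, 9)
  read <- substr(genome, 51, 450)
  cr <- correct_read(read, idx, name = "r1")
  expect_false(cr$skipped)
  expect_equal(cr$seq, read)  # unchanged, all upper case
})

test_that("a single interior substitution is corrected back to the genome", {
  set.seed(46)
  genome <- random_dna(600)
  idx <- seq_index(genome, 9)
  truth <- substr(genome, 51, 450)
  read <- truth
  substr(read, 200, 200) <- setdiff(c("A", "C", "G", "T"),
                                    substr(read, 200, 200))[1]
  cr <- correct_read(read, idx)
  expect_equal(toupper(cr$seq), truth)
})

test_that("reads without any solid k-mer are skipped in lower case", {
  idx <- count_kmers(character(0), kmer_spec(9, 1))
  cr <- correct_read("ACGTACGTACGTACGT", idx, name = "r")
  expect_true(cr$skipped)
  expect_equal(cr$seq, tolower("ACGTACGTACGTACGT"))
})

test_that("splicing keeps bases outside replaced spans and length arithmetic", {
  set.seed(47)
  genome <- random_dna(800)
  k <- 9L
  idx <- seq_index(genome, k)
  truth <- substr(genome, 101, 700)
  read <- truth
  # one substitution and one deletion, far apart and away from the ends
  substr(read, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                    substr(read, 150, 150))[1]
  read <- paste0(substr(read, 1, 399), substring(read, 401))
  cr <- correct_read(read, idx)
  expect_equal(toupper(cr$seq), truth)
  expect_equal(nchar(cr$seq), nchar(read) + 1L)  # deletion restored

  # determinism: identical inputs give byte-identical output
  cr2 <- correct_read(read, idx)
  expect_identical(cr$seq, cr2$seq)
})
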