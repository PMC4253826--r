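#' Simulation configuration
#'
#' Study conditions for the synthetic data generator: a random genome, a
#' high-coverage accurate short-read set, and a low-coverage long-read
#' set with a high, insertion-skewed error rate.  Defaults emulate a
#' bacterial-scale experiment: a 50 kb genome; 75 bp short reads at 50x
#' coverage with 0.5% substitution errors; 2-8 kb long reads at 15%
#' error, split 55% insertions / 30% deletions / 15% substitutions as in
#' PacBio-like chemistry where insertions dominate, then deletions.
#'
#' @param genome_length genome size in bases.
#' @param gc GC fraction of the genome.
#' @param sr_coverage,sr_length,sr_sub_rate short-read fold coverage,
#'   read length (bases) and per-base substitution rate.
#' @param lr_coverage long-read fold coverage.
#' @param lr_error_rate per-base error probability of long reads.
#' @param lr_ins_frac,lr_del_frac,lr_sub_frac fractions of errors that
#'   are insertions, deletions and substitutions; must sum to 1.
#' @param lr_length_range length 2 vector, uniform range of long-read
#'   target lengths in bases.
#' @param seed integer seed; the generator is fully deterministic per
#'   seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 50000L, gc = 0.5,
                       sr_coverage = 50, sr_length = 75L,
                       sr_sub_rate = 0.005,
                       lr_coverage = 10, lr_error_rate = 0.15,
                       lr_ins_frac = 0.55, lr_del_frac = 0.30,
                       lr_sub_frac = 0.15,
                       lr_length_range = c(2000L, 8000L),
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length), gc = gc,
              sr_coverage = sr_coverage, sr_length = as.integer(sr_length),
              sr_sub_rate = sr_sub_rate,
              lr_coverage = lr_coverage, lr_error_rate = lr_error_rate,
              lr_ins_frac = lr_ins_frac, lr_del_frac = lr_del_frac,
              lr_sub_frac = lr_sub_frac,
              lr_length_range = as.integer(lr_length_range),
              seed = as.integer(seed))
  fr <- c(cfg$gc, cfg$sr_sub_rate, cfg$lr_error_rate, cfg$lr_ins_frac,
          cfg$lr_del_frac, cfg$lr_sub_frac)
  if (any(is.na(fr)) || any(fr < 0) || any(fr > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (abs(cfg$lr_ins_frac + cfg$lr_del_frac + cfg$lr_sub_frac - 1) > 1e-8)
    stop("error-type fractions must sum to 1", call. = FALSE)
  if (length(cfg$lr_length_range) != 2L ||
      cfg$lr_length_range[1L] > cfg$lr_length_range[2L])
    stop("`lr_length_range` must be c(min, max) with min <= max",
         call. = FALSE)
  if (is.na(cfg$seed) || cfg$seed < 0L || cfg$seed > 2147483600L)
    stop("`seed` must be a non-negative integer below 2^31 - 47",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate a random genome
#'
#' i.i.d. bases at the requested GC content; deterministic per
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a single DNA string of `genome_length` bases.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_length == 0L) return("")
  set.seed(config$seed)
  p <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
         (1 - config$gc) / 2)
  paste(sample(BASES, config$genome_length, replace = TRUE, prob = p),
        collapse = "")
}

#' Simulate short reads
#'
#' Uniformly placed fixed-length reads from both strands with
#' independent per-base substitution errors at `sr_sub_rate`.  The read
#' count is `round(sr_coverage * genome length / sr_length)`.
#'
#' @param genome genome string.
#' @param config a [sim_config()].
#' @return named character vector of reads (`sr_1`, `sr_2`, ...).
#' @export
simulate_short_reads <- function(genome, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  L <- nchar(genome)
  len <- config$sr_length
  if (L < len) stop("genome shorter than the short-read length", call. = FALSE)
  set.seed(config$seed + 1L)
  nreads <- as.integer(round(config$sr_coverage * L / len))
  starts <- sample.int(L - len + 1L, nreads, replace = TRUE)
  reads <- substring(genome, starts, starts + len - 1L)
  minus <- stats::runif(nreads) < 0.5
  reads[minus] <- revcomp(reads[minus])
  if (config$sr_sub_rate > 0) {
    nerr <- stats::rbinom(1L, nreads * len, config$sr_sub_rate)
    if (nerr > 0L) {
      at <- sample.int(nreads * len, nerr)  # without replacement
      ridx <- (at - 1L) %/% len + 1L
      pos <- (at - 1L) %% len + 1L
      old <- substring(reads[ridx], pos, pos)
      new <- vapply(old, function(b) sample(setdiff(BASES, b), 1L), "",
                    USE.NAMES = FALSE)
      for (e in seq_len(nerr))
        substr(reads[ridx[e]], pos[e], pos[e]) <- new[e]
    }
  }
  stats::setNames(reads, paste0("sr_", seq_len(nreads)))
}

#' Simulate long reads with ground truth
#'
#' Each read is drawn from a uniformly placed genome interval on a
#' random strand, with length uniform over `lr_length_range`.  Errors
#' follow a per-base process: with probability `lr_error_rate` a base
#' receives an error, typed by the insertion/deletion/substitution
#' fractions (an insertion adds a random base before the true base; a
#' deletion drops the true base; a substitution replaces it by a
#' different random base).  Every edit is recorded so that replaying the
#' edits on the true (strand-oriented) genome interval reproduces the
#' read exactly.
#'
#' @param genome genome string, at least `max(lr_length_range)` long.
#' @param config a [sim_config()].
#' @return list with `reads` (named character vector `lr_1`, ...) and
#'   `truth`, a data frame with columns `name`, `start`, `end` (0-based
#'   half-open genome interval), `strand` (`+`/`-`) and `edits`
#'   (semicolon-separated `pos:op:base` records in truth-region
#'   coordinates; `"."` if none).
#' @export
simulate_long_reads <- function(genome, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  L <- nchar(genome)
  rng <- config$lr_length_range
  if (L < rng[2L]) stop("genome shorter than the maximum read length",
                        call. = FALSE)
  set.seed(config$seed + 2L)
  nreads <- max(1L, as.integer(round(config$lr_coverage * L / mean(rng))))
  reads <- character(nreads)
  truth <- data.frame(name = paste0("lr_", seq_len(nreads)),
                      start = integer(nreads), end = integer(nreads),
                      strand = character(nreads), edits = character(nreads))
  for (i in seq_len(nreads)) {
    len <- if (rng[1L] == rng[2L]) rng[1L] else
      sample(seq.int(rng[1L], rng[2L]), 1L)
    start <- sample.int(L - len + 1L, 1L) - 1L
    strand <- if (stats::runif(1L) < 0.5) "+" else "-"
    region <- substr(genome, start + 1L, start + len)
    if (strand == "-") region <- revcomp(region)
    sim <- mutate_region(region, config)
    reads[i] <- sim$read
    truth$start[i] <- start; truth$end[i] <- start + len
    truth$strand[i] <- strand; truth$edits[i] <- sim$edits
  }
  names(reads) <- truth$name
  list(reads = reads, truth = truth)
}

# Apply the per-base error process to one truth region; returns the read
# and the edit record string.
mutate_region <- function(region, config) {
  len <- nchar(region)
  err <- stats::runif(len) < config$lr_error_rate
  if (!any(err))
    return(list(read = region, edits = "."))
  chars <- strsplit(region, "")[[1L]]
  pieces <- chars
  pos <- which(err)
  type <- sample(c("I", "D", "S"), length(pos), replace = TRUE,
                 prob = c(config$lr_ins_frac, config$lr_del_frac,
                          config$lr_sub_frac))
  base <- character(length(pos))
  for (e in seq_along(pos)) {
    p <- pos[e]
    if (type[e] == "I") {
      base[e] <- sample(BASES, 1L)
      pieces[p] <- paste0(base[e], chars[p])
    } else if (type[e] == "D") {
      base[e] <- "-"
      pieces[p] <- ""
    } else {
      base[e] <- sample(setdiff(BASES, chars[p]), 1L)
      pieces[p] <- base[e]
    }
  }
  list(read = paste(pieces, collapse = ""),
       edits = paste(sprintf("%d:%s:%s", pos - 1L, type, base),
                     collapse = ";"))
}

#' Replay recorded edits on a truth region
#'
#' Reconstructs a simulated read from its strand-oriented genome
#' interval and the edit records of the truth table.
#'
#' @param region strand-oriented genome substring.
#' @param edits edit record string (`pos:op:base` joined by `;`, or `.`).
#' @return the read sequence.
#' @export
apply_edits <- function(region, edits) {
  if (is.na(edits) || edits == "." || edits == "") return(region)
  chars <- strsplit(region, "")[[1L]]
  pieces <- chars
  for (ed in strsplit(edits, ";", fixed = TRUE)[[1L]]) {
    f <- strsplit(ed, ":", fixed = TRUE)[[1L]]
    p <- as.integer(f[1L]) + 1L
    if (f[2L] == "I") pieces[p] <- paste0(f[3L], chars[p])
    else if (f[2L] == "D") pieces[p] <- ""
    else pieces[p] <- f[3L]
  }
  paste(pieces, collapse = "")
}

#' Parse an edit record string into a data frame
#'
#' @param edits edit record string as stored in the truth table.
#' @return data frame with 0-based `pos`, `op` (`I`/`D`/`S`) and `base`.
#' @export
parse_edits <- function(edits) {
  if (is.na(edits) || edits == "." || edits == "")
    return(data.frame(pos = integer(0), op = character(0),
                      base = character(0)))
  f <- do.call(rbind, strsplit(strsplit(edits, ";", fixed = TRUE)[[1L]],
                               ":", fixed = TRUE))
  data.frame(pos = as.integer(f[, 1L]), op = f[, 2L], base = f[, 3L])
}

#' Write / read the long-read truth sidecar
#'
#' Tab-separated table with columns name, start, end, strand, edits.
#'
#' @param truth truth data frame from [simulate_long_reads()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "integer",
                                   "character", "character"))
}
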