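#' Position-level classification counts
#'
#' Container for the TP/FP/TN/FN counts of a correction evaluation.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return an object of class `eval_counts`.
#' @export
eval_counts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(v)) || any(v < 0))
    stop("counts must be non-negative", call. = FALSE)
  structure(as.list(v), class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("TP %s  FP %s  TN %s  FN %s\n",
              format(x$tp, big.mark = ","), format(x$fp, big.mark = ","),
              format(x$tn, big.mark = ","), format(x$fn, big.mark = ",")))
  if (x$tp + x$fn > 0)
    cat(sprintf("sensitivity %.4f  gain %.4f\n", sensitivity(x), gain(x)))
  invisible(x)
}

#' @export
"+.eval_counts" <- function(e1, e2) {
  eval_counts(e1$tp + e2$tp, e1$fp + e2$fp, e1$tn + e2$tn, e1$fn + e2$fn)
}

# Turn an op string (M/X/D/I per column, truth-anchored) into the
# per-truth-position state and the insertion counts between positions.
ops_to_columns <- function(ops, L) {
  v <- strsplit(ops, "")[[1L]]
  consumes <- v != "I"
  state <- v[consumes]
  if (length(state) != L)
    stop("alignment does not consume the whole truth region", call. = FALSE)
  ins <- tabulate(cumsum(consumes)[!consumes] + 1L, nbins = L + 1L)
  list(state = state, ins = ins)
}

# Op string of original vs truth built directly from simulator edits.
ops_from_edits <- function(edits, L) {
  ed <- parse_edits(edits)
  state <- rep("M", L)
  ins <- integer(L + 1L)
  if (nrow(ed) > 0L) {
    state[ed$pos[ed$op == "S"] + 1L] <- "X"
    state[ed$pos[ed$op == "D"] + 1L] <- "D"
    for (p in ed$pos[ed$op == "I"]) ins[p + 1L] <- ins[p + 1L] + 1L
  }
  list(state = state, ins = ins)
}

#' Classify positions of a corrected read
#'
#' Builds a three-way correspondence of original read, corrected read and
#' the true genomic region, anchored on the truth sequence: the original
#' and the corrected read are each aligned to the truth (unit-cost edit
#' alignment with a deterministic traceback preferring match/mismatch,
#' then deletion, then insertion; the original's alignment is taken from
#' the simulator's recorded edits when supplied), and the two alignments
#' are merged column-wise on truth coordinates, padding insertions at the
#' same junction left-aligned.  Per column: original erroneous and
#' corrected correct is a TP; both erroneous an FN; original correct and
#' corrected erroneous an FP; both correct a TN.  An empty corrected read
#' counts every original-error column as FN and every other column as TN;
#' a corrected read identical to the original shares the original's
#' alignment (so nothing is counted as corrected or miscorrected).
#'
#' @param original the original (uncorrected) read sequence.
#' @param corrected the corrected sequence (case ignored).
#' @param truth_region the strand-oriented genome substring the read was
#'   drawn from.
#' @param original_edits optional simulator edit record for
#'   original-vs-truth (see [simulate_long_reads()]); when absent the
#'   alignment is computed by dynamic programming.
#' @return an [eval_counts()].
#' @export
classify_positions <- function(original, corrected, truth_region,
                               original_edits = NULL) {
  original <- toupper(as.character(original)[1L])
  corrected <- toupper(as.character(corrected)[1L])
  truth_region <- toupper(as.character(truth_region)[1L])
  L <- nchar(truth_region)
  o <- if (!is.null(original_edits))
    ops_from_edits(original_edits, L)
  else
    ops_to_columns(cx_align_ops(original, truth_region), L)
  oerr_state <- o$state != "M"
  n_oerr <- sum(oerr_state) + sum(o$ins)
  if (nchar(corrected) == 0L) {
    n_cols <- L + sum(o$ins)
    return(eval_counts(tp = 0, fp = 0, tn = n_cols - n_oerr, fn = n_oerr))
  }
  co <- if (corrected == original) o  # identical strings share one alignment
  else ops_to_columns(cx_align_ops(corrected, truth_region), L)
  cerr_state <- co$state != "M"
  tp <- sum(oerr_state & !cerr_state)
  fn <- sum(oerr_state & cerr_state)
  fp <- sum(!oerr_state & cerr_state)
  tn <- sum(!oerr_state & !cerr_state)
  both <- pmin(o$ins, co$ins)
  fn <- fn + sum(both)
  tp <- tp + sum(o$ins - both)
  fp <- fp + sum(co$ins - both)
  eval_counts(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Sensitivity of a correction
#'
#' `TP / (TP + FN)`: the fraction of erroneous positions that were
#' corrected.
#'
#' @param c an [eval_counts()].
#' @return fraction in `[0, 1]`; `NA` with a warning when `TP + FN = 0`.
#' @export
sensitivity <- function(c) {
  stopifnot(inherits(c, "eval_counts"))
  if (c$tp + c$fn == 0) {
    warning("sensitivity undefined: no erroneous positions (TP + FN = 0)")
    return(NA_real_)
  }
  c$tp / (c$tp + c$fn)
}

#' Gain of a correction
#'
#' `(TP - FP) / (TP + FN)`: how well errors were removed without
#' introducing new ones; can be negative.
#'
#' @param c an [eval_counts()].
#' @return fraction `<= 1`; `NA` with a warning when `TP + FN = 0`.
#' @export
gain <- function(c) {
  stopifnot(inherits(c, "eval_counts"))
  if (c$tp + c$fn == 0) {
    warning("gain undefined: no erroneous positions (TP + FN = 0)")
    return(NA_real_)
  }
  (c$tp - c$fp) / (c$tp + c$fn)
}

#' Evaluate a corrected read set against simulation truth
#'
#' Runs [classify_positions()] for every read and aggregates the counts.
#'
#' @param originals named character vector of original reads.
#' @param corrected a `corrected_read_set`, or a named character vector
#'   of corrected sequences (case ignored).
#' @param truth truth data frame from [simulate_long_reads()] (or
#'   [read_truth()]).
#' @param genome the genome string the truth coordinates refer to.
#' @param use_edits use the recorded simulator edits for the
#'   original-vs-truth alignment (default `TRUE`).
#' @return list with `per_read` (data frame of counts, sensitivity and
#'   gain per read), `total` (an [eval_counts()]), `sensitivity` and
#'   `gain`.
#' @export
evaluate_correction <- function(originals, corrected, truth, genome,
                                use_edits = TRUE) {
  cseq <- if (is.character(corrected)) corrected else as.character(corrected)
  originals <- stats::setNames(as.character(originals), names(originals))
  if (is.null(names(cseq)) || is.null(names(originals)))
    stop("reads must be named to match the truth table", call. = FALSE)
  per <- data.frame(name = truth$name, tp = NA_real_, fp = NA_real_,
                    tn = NA_real_, fn = NA_real_)
  total <- eval_counts()
  for (i in seq_len(nrow(truth))) {
    nm <- truth$name[i]
    if (!nm %in% names(originals) || !nm %in% names(cseq)) next
    region <- substr(genome, truth$start[i] + 1L, truth$end[i])
    if (truth$strand[i] == "-") region <- revcomp(region)
    cc <- classify_positions(originals[[nm]], cseq[[nm]], region,
                             original_edits = if (use_edits)
                               truth$edits[i] else NULL)
    per$tp[i] <- cc$tp; per$fp[i] <- cc$fp
    per$tn[i] <- cc$tn; per$fn[i] <- cc$fn
    total <- total + cc
  }
  per$sensitivity <- ifelse(per$tp + per$fn > 0,
                            per$tp / (per$tp + per$fn), NA_real_)
  per$gain <- ifelse(per$tp + per$fn > 0,
                     (per$tp - per$fp) / (per$tp + per$fn), NA_real_)
  list(per_read = per, total = total,
       sensitivity = sensitivity(total), gain = gain(total))
}
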