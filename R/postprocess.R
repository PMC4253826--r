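#' Trim weak ends of a corrected read
#'
#' Removes the maximal lower-case (weak) prefix and suffix of a
#' case-encoded corrected sequence; inner weak stretches bordered by
#' solid bases are left intact.  One output per input; an all-weak read
#' trims to the empty string (the record is kept).
#'
#' @param x a `corrected_read`, or a character vector of case-encoded
#'   sequences.
#' @return same type as the input, with trimmed sequence(s).
#' @examples
#' trim_corrected("acGGTtaCCg")  # "GGTtaCC"
#' @export
trim_corrected <- function(x) {
  if (inherits(x, "corrected_read")) {
    x$seq <- trim_corrected(x$seq)
    return(x)
  }
  if (inherits(x, "corrected_read_set")) {
    out <- lapply(unclass(x), trim_corrected)
    class(out) <- "corrected_read_set"
    return(out)
  }
  if (!is.character(x)) x <- as.character(x)
  sub("[a-z]+$", "", sub("^[a-z]+", "", x))
}

#' Extract solid runs of a corrected read as separate sequences
#'
#' Splits a case-encoded corrected sequence into its maximal runs of
#' upper-case (solid) bases, in order.  Pieces are named
#' `<read>_split<i>` with `i` starting at 0; an all-weak read yields no
#' pieces.
#'
#' @param x a `corrected_read`, a `corrected_read_set`, or a single
#'   case-encoded string.
#' @param name read name used for piece naming when `x` is a bare string.
#' @return named character vector of solid pieces.
#' @examples
#' trim_split("acGGTtaCCg", name = "r")  # r_split0 = "GGT", r_split1 = "CC"
#' @export
trim_split <- function(x, name = "read") {
  if (inherits(x, "corrected_read")) {
    nm <- if (is.na(x$name)) name else x$name
    return(trim_split(x$seq, name = nm))
  }
  if (inherits(x, "corrected_read_set")) {
    pieces <- lapply(unclass(x), trim_split)
    return(do.call(c, unname(pieces)))
  }
  s <- as.character(x)[1L]
  m <- gregexpr("[A-Z]+", s)[[1L]]
  if (m[1L] == -1L) return(stats::setNames(character(0), character(0)))
  pieces <- regmatches(s, gregexpr("[A-Z]+", s))[[1L]]
  stats::setNames(pieces, paste0(name, "_split", seq_along(pieces) - 1L))
}
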