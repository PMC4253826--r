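#' Read sequences from FASTA or FASTQ
#'
#' FASTQ (by extension `.fq`/`.fastq`, optionally gzipped) or FASTA;
#' qualities are ignored and sequences are returned upper case.
#'
#' @param path input file (gzip accepted).
#' @return named character vector (full headers kept as names).
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(x), names(x))
}

#' Read case-encoded corrected sequences
#'
#' Reads a FASTA file preserving the upper/lower case solidity encoding
#' (plain [read_sequences()] normalises case).
#'
#' @param path corrected-read FASTA file.
#' @return named character vector with case preserved.
#' @export
read_corrected <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences as FASTA
#'
#' Case is preserved (so the solidity encoding of corrected reads
#' survives); lines wrap at 80 columns.
#'
#' @param x named character vector, `corrected_read_set`, or anything
#'   with an `as.character` method yielding named sequences.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(x, path, width = 80L) {
  seqs <- if (is.character(x)) x else as.character(x)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = width)
  invisible(path)
}
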