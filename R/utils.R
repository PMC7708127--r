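#' @importFrom stats median pf plnorm pnorm pwilcox qlnorm rbinom runif setNames
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Phred+33 encoding helpers -------------------------------------------------

phred_to_char <- function(q) {
  q <- pmin(pmax(as.integer(q), 0L), 93L)
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

qual_string <- function(q, len) {
  strrep(phred_to_char(q), len)
}

char_to_phred <- function(s) {
  if (is.na(s) || s == "*" || !nzchar(s)) return(integer(0))
  as.integer(charToRaw(s)) - 33L
}

## FASTA helpers --------------------------------------------------------------

#' Read a FASTA file into a DNAStringSet
#'
#' Names are truncated at the first whitespace, matching aligner behaviour.
#'
#' @param path FASTA file (optionally gzipped).
#' @return a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence name in ", path, ": ",
         names(x)[duplicated(names(x))][1])
  x
}

#' Write a DNAStringSet to FASTA with fixed 60-column wrapping
#'
#' @param x DNAStringSet (or named character vector).
#' @param path output file.
#' @param width line width; fixed default 60 for reproducible output.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

as_dnastringset <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(read_fasta(genome))
  if (is.character(genome)) return(Biostrings::DNAStringSet(genome))
  if (methods::is(genome, "DNAStringSet")) return(genome)
  stop("cannot interpret genome input of class ", class(genome)[1])
}

#' @importFrom methods is
NULL
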