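#' Duplex DNA sequence
#'
#' A light container for a double-stranded DNA molecule. Positions are
#' 1-based on the forward strand; the reverse strand is the reverse
#' complement and is always addressed by the forward coordinate of its
#' paired base, so both strands share a single coordinate axis.
#'
#' @param forward Character scalar over `{A,C,G,T}` (case-insensitive;
#'   stored uppercase).
#' @return An object of class `duplex_sequence` with elements `forward`
#'   (string) and `length` (bp).
#' @examples
#' d <- duplex_sequence("GGATCC")
#' d$length
#' @export
duplex_sequence <- function(forward) {
  if (!is.character(forward) || length(forward) != 1L || is.na(forward))
    stop("`forward` must be a single character string")
  forward <- toupper(forward)
  check_acgt(forward)
  structure(list(forward = forward, length = nchar(forward)),
            class = "duplex_sequence")
}

#' @export
print.duplex_sequence <- function(x, ...) {
  cat(sprintf("<duplex_sequence> %d bp\n", x$length))
  if (x$length <= 60) cat(" ", x$forward, "\n")
  else cat(" ", substr(x$forward, 1, 30), "...",
           substr(x$forward, x$length - 29, x$length), "\n", sep = "")
  invisible(x)
}

check_acgt <- function(s) {
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L)
    stop(sprintf("non-ACGT character '%s' at position %d",
                 substr(s, bad, bad), bad))
  invisible(TRUE)
}

#' Reverse complement of a DNA string
#'
#' @param seq A character string over `{A,C,G,T}` or a [duplex_sequence()].
#' @return The Watson-Crick reverse complement as a character string.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  if (inherits(seq, "duplex_sequence")) seq <- seq$forward
  if (!is.character(seq) || length(seq) != 1L)
    stop("`seq` must be a single character string")
  seq <- toupper(seq)
  check_acgt(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Base at each position of one strand
#'
#' Returns the base read 5'->3' along the requested strand at the strand's
#' own positions 1..L (for the reverse strand, position k is the k-th base
#' of the reverse complement).
#'
#' @param seq A [duplex_sequence()].
#' @param strand `"forward"` or `"reverse"`.
#' @return Character vector of single bases, length `seq$length`.
#' @export
strand_bases <- function(seq, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  s <- if (strand == "forward") seq$forward else reverse_complement(seq)
  strsplit(s, "", fixed = TRUE)[[1L]]
}

#' Read a duplex sequence from a FASTA file
#'
#' Reads the first record of a FASTA file into a [duplex_sequence()].
#'
#' @param path Path to a FASTA file.
#' @return A `duplex_sequence`.
#' @export
read_fasta_duplex <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  duplex_sequence(as.character(set[[1L]]))
}

#' The 399-bp study insert
#'
#' The plasmid insert used throughout the package examples: a 399-bp
#' duplex carrying 11 transcription-factor binding sites and the
#' Drew-Dickerson dodecamer, flanked by BamHI (GGATCC) and HindIII
#' (AAGCTT) restriction sites. Shipped as a plain FASTA file under
#' `inst/extdata`.
#'
#' @return A [duplex_sequence()] of length 399.
#' @export
insert_399 <- function() {
  read_fasta_duplex(system.file("extdata", "insert399.fasta",
                                package = "grooveprint", mustWork = TRUE))
}
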