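#' @import methods
#' @importFrom stats runif var predict setNames median rgamma
#' @importFrom utils read.table write.table packageVersion head
NULL

#' Run code with a temporary RNG seed
#'
#' All stochastic steps in the package route their randomness through this
#' helper so that a single integer seed makes a whole run reproducible
#' without clobbering the caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# md5 of a serialized R object, via a temp file (base R only)
objectHash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}

# doubles <-> strings that round-trip IEEE 754 exactly (17 significant digits)
num2chr <- function(x) sprintf("%.17g", x)
chr2num <- function(x) as.numeric(x)

#' Write sequences as 60-column wrapped FASTA
#'
#' @param x a `DNAStringSet` or `AAStringSet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a nucleotide FASTA as uppercase transcripts
#'
#' Accepts single-line and multi-line FASTA dialects. Sequence names are
#' truncated at the first whitespace; sequences are uppercased on ingest.
#'
#' @param path FASTA file path.
#' @return a named `DNAStringSet`.
#' @export
readTranscripts <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  if (anyDuplicated(names(x)))
    stop("duplicate transcript ids in ", path)
  if (any(Biostrings::width(x) == 0L))
    stop("zero-length sequence in ", path)
  x
}

#' Read an amino-acid FASTA
#'
#' @param path FASTA file path.
#' @return a named `AAStringSet`.
#' @export
readProteins <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

# vectorized in-frame codon split of one character sequence at offset (0..2)
frameCodons <- function(seq, offset = 0L) {
  L <- nchar(seq)
  n <- (L - offset) %/% 3L
  if (n <= 0L) return(character(0))
  starts <- offset + 3L * seq_len(n) - 2L
  substring(seq, starts, starts + 2L)
}

revcompChr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
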