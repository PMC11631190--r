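#' NCBI genetic-code tables
#'
#' Returns the codon-to-amino-acid map for an NCBI translation table as a
#' named character vector over the 64 ACGT codons, with stop codons rendered
#' `"*"`. Tables 1-26 come from Biostrings; tables 29 (Mesodinium nuclear,
#' TAA/TAG = Tyr) and 30 (Peritrich nuclear, TAA/TAG = Glu) are defined here
#' from the NCBI definitions since Biostrings 2.70 does not ship them. Table 6
#' is the ciliate/dasycladacean code (TAA/TAG = Gln, only TGA is stop).
#'
#' @param tableId NCBI translation-table id, as integer or string
#'   (e.g. `1`, `"6"`).
#' @return named character vector of length 64 mapping codons to one-letter
#'   amino acids; attribute `"id"` carries the table id.
#' @examples
#' geneticCode(6)[c("TAA", "TAG", "TGA")]
#' @export
geneticCode <- function(tableId = 1) {
  id <- as.character(tableId)
  if (id %in% c("29", "30")) {
    code <- Biostrings::getGeneticCode("1")
    code[c("TAA", "TAG")] <- if (id == "29") "Y" else "E"
  } else {
    code <- tryCatch(Biostrings::getGeneticCode(id),
                     error = function(e) stop("unknown genetic-code table: ", id))
  }
  code <- code[CODON_VOCABULARY]
  stopifnot(!anyNA(code))
  attr(code, "id") <- id
  code
}

#' Translate an in-frame nucleotide sequence
#'
#' Codons containing any non-ACGT character translate to `"X"`; stop codons
#' are rendered `"*"`. The sequence length must be a multiple of three.
#'
#' @param ntSeq character vector of nucleotide sequences (uppercase ACGTN...).
#' @param code a genetic code from [geneticCode()], or a table id.
#' @return character vector of amino-acid sequences.
#' @examples
#' translateSeq("ATGAAATGA")           # "MK*"
#' translateSeq("ATGTAATGA", code = 6) # "MQ*"
#' @export
translateSeq <- function(ntSeq, code = geneticCode(1)) {
  if (!is.character(code) || is.null(names(code))) code <- geneticCode(code)
  bad <- nchar(ntSeq) %% 3L != 0L
  if (any(bad))
    stop("sequence length not divisible by 3 for ",
         sum(bad), " sequence(s)")
  vapply(ntSeq, function(s) {
    cod <- frameCodons(s, 0L)
    aa <- unname(code[cod])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# codons whose amino acid is invariant to the third base under `code`
# (the four-fold degenerate set used for GC3s)
fourfoldCodons <- function(code) {
  p12 <- unique(substr(CODON_VOCABULARY, 1L, 2L))
  four <- unlist(lapply(p12, function(d) {
    fam <- paste0(d, DNA_BASES)
    if (length(unique(unname(code[fam]))) == 1L) fam else character(0)
  }))
  four
}
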