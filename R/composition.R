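#' Codon-position GC composition of in-frame sequences
#'
#' Computes, per ORF: GC12 (percent G+C over codon positions 1 and 2), GC3
#' (percent G+C at codon position 3), and GC3s (GC3 restricted to four-fold
#' degenerate codons, i.e. codons whose amino acid is invariant to any
#' third-position base under the active genetic code). Codons containing a
#' non-ACGT character are excluded from all tallies; GC3s is `NA` when a
#' sequence has no four-fold degenerate codon. These joint (GC12, GC3)
#' distributions are the composition "fingerprints" used to spot
#' contamination in mixed datasets.
#'
#' @param x an [OrfSet-class], `DNAStringSet`, or character vector of
#'   in-frame nucleotide sequences (lengths divisible by 3).
#' @param code genetic code from [geneticCode()], or a table id.
#' @return data.frame: `orf_id`, `n_codons` (ACGT codons tallied), `gc12`,
#'   `gc3`, `gc3s` (percent).
#' @examples
#' computeComposition(c(a = "ATGGCC"))  # gc12 50, gc3 100
#' @export
computeComposition <- function(x, code = geneticCode(1)) {
  if (is(x, "OrfSet")) x <- ntSeqs(x)
  if (!is.character(x)) {
    ids <- names(x)
    x <- as.character(x)
    names(x) <- ids
  }
  if (!is.character(code) || is.null(names(code))) code <- geneticCode(code)
  if (any(nchar(x) %% 3L != 0L))
    stop("sequence length not divisible by 3")
  four <- fourfoldCodons(code)
  gc <- c(A = 0, C = 1, G = 1, T = 0)
  res <- lapply(seq_along(x), function(i) {
    cod <- frameCodons(x[[i]], 0L)
    cod <- cod[!grepl("[^ACGT]", cod)]
    n <- length(cod)
    if (n == 0L)
      return(data.frame(n_codons = 0L, gc12 = NA_real_, gc3 = NA_real_,
                        gc3s = NA_real_))
    b1 <- substr(cod, 1L, 1L); b2 <- substr(cod, 2L, 2L)
    b3 <- substr(cod, 3L, 3L)
    gc12 <- 100 * mean(c(gc[b1], gc[b2]))
    gc3 <- 100 * mean(gc[b3])
    isFour <- cod %in% four
    gc3s <- if (any(isFour)) 100 * mean(gc[b3[isFour]]) else NA_real_
    data.frame(n_codons = n, gc12 = gc12, gc3 = gc3, gc3s = gc3s)
  })
  res <- do.call(rbind, res)
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_along(x))
  cbind(data.frame(orf_id = ids, stringsAsFactors = FALSE), res)
}

#' Select training sequences inside composition windows
#'
#' Draws a seeded uniform sample of `n` ORF ids from those whose GC12 and
#' GC3 both fall inside the given windows (bounds inclusive). This mirrors
#' selecting training clusters by eye from a composition fingerprint plot
#' and sampling within the chosen thresholds. If fewer than `n` ids
#' qualify, all are returned with a warning.
#'
#' @param metrics data.frame from [computeComposition()].
#' @param gc12Window,gc3Window numeric `c(lo, hi)` windows in percent.
#' @param n number of ids to draw.
#' @param seed integer seed.
#' @return character vector of selected orf ids.
#' @export
selectByComposition <- function(metrics, gc12Window, gc3Window, n,
                                seed = 1L) {
  stopifnot(length(gc12Window) == 2L, gc12Window[1] <= gc12Window[2],
            length(gc3Window) == 2L, gc3Window[1] <= gc3Window[2], n >= 1L)
  ok <- !is.na(metrics$gc12) & !is.na(metrics$gc3) &
    metrics$gc12 >= gc12Window[1] & metrics$gc12 <= gc12Window[2] &
    metrics$gc3 >= gc3Window[1] & metrics$gc3 <= gc3Window[2]
  ids <- metrics$orf_id[ok]
  if (!length(ids))
    stop(sprintf("no sequences inside GC12 [%g, %g] and GC3 [%g, %g]",
                 gc12Window[1], gc12Window[2], gc3Window[1], gc3Window[2]))
  if (length(ids) < n) {
    warning("only ", length(ids), " sequences inside the windows; ",
            "returning all of them")
    return(ids)
  }
  withSeed(seed, sample(ids, n))
}

#' Write a composition table as TSV
#'
#' @param metrics data.frame from [computeComposition()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeComposition <- function(metrics, path) {
  write.table(metrics, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
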