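#' Enumerate ORFs in all six reading orientations
#'
#' Scans each transcript in its three forward and three reverse-complement
#' frames. In every frame, the codon stream is segmented at in-frame stop
#' codons; within each stop-bounded segment the ORF runs from the first
#' start codon (ATG by default) through the segment's terminal stop and is
#' reported as complete. With `partial = TRUE`, stop-bounded segments that
#' lack a start codon are additionally reported in full as partial ORFs, as
#' is the trailing stretch of each frame that ends at the transcript edge
#' without reaching a stop. Only ORFs spanning at least `minLen` nucleotides
#' (terminal stop included, when present) are returned.
#'
#' Coordinates are 1-based inclusive on the forward strand of the transcript;
#' the sign of `frame` encodes the strand, and for negative frames `nt_seq`
#' is the reverse complement of the forward-strand slice.
#'
#' @param transcripts named `DNAStringSet`.
#' @param code genetic code from [geneticCode()], or a table id.
#' @param minLen minimum ORF length in nucleotides, a positive multiple of 3
#'   (default 150).
#' @param partial also return partial ORFs (default `FALSE`: complete only).
#' @param startCodons codon(s) accepted as translation starts.
#' @return an [OrfSet-class].
#' @examples
#' tx <- Biostrings::DNAStringSet(c(t1 = "CCATGAAATAGGC"))
#' orfInfo(enumerateOrfs(tx, minLen = 9))
#' @export
enumerateOrfs <- function(transcripts, code = geneticCode(1), minLen = 150L,
                          partial = FALSE, startCodons = START_CODONS) {
  if (!is.character(code) || is.null(names(code))) code <- geneticCode(code)
  stopifnot(minLen >= 3L, minLen %% 3L == 0L)
  codeId <- attr(code, "id")
  res <- vector("list", length(transcripts))
  txIds <- names(transcripts)
  txChr <- as.character(transcripts)
  for (t in seq_along(transcripts)) {
    s <- txChr[[t]]
    L <- nchar(s)
    rc <- revcompChr(s)
    rows <- list()
    for (fr in 1:6) {
      strand <- if (fr <= 3L) 1L else -1L
      off <- (fr - 1L) %% 3L
      str <- if (strand == 1L) s else rc
      hits <- frameOrfHits(str, off, code, minLen, partial, startCodons)
      if (is.null(hits)) next
      # hits: codon-index spans on the reading strand -> strand coordinates
      sPos <- off + 3L * (hits$from - 1L) + 1L
      ePos <- off + 3L * hits$to
      if (strand == 1L) {
        rows[[fr]] <- data.frame(frame = off + 1L, start = sPos, end = ePos,
                                 complete = hits$complete,
                                 nt = substring(str, sPos, ePos),
                                 stringsAsFactors = FALSE)
      } else {
        rows[[fr]] <- data.frame(frame = -(off + 1L),
                                 start = L - ePos + 1L, end = L - sPos + 1L,
                                 complete = hits$complete,
                                 nt = substring(str, sPos, ePos),
                                 stringsAsFactors = FALSE)
      }
    }
    rows <- do.call(rbind, rows)
    if (is.null(rows) || nrow(rows) == 0L) { res[[t]] <- NULL; next }
    # stable reporting order: frames +1,+2,+3,-1,-2,-3, then position
    frameOrd <- match(rows$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
    rows <- rows[order(frameOrd, rows$start), , drop = FALSE]
    rows$transcript_id <- txIds[t]
    rows$orf_id <- sprintf("%s.orf%d", txIds[t], seq_len(nrow(rows)))
    res[[t]] <- rows
  }
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L) {
    return(OrfSet(
      info = data.frame(orf_id = character(0), transcript_id = character(0),
                        frame = integer(0), start = integer(0),
                        end = integer(0), complete = logical(0)),
      ntSeq = Biostrings::DNAStringSet(), aaSeq = Biostrings::AAStringSet(),
      codeId = codeId))
  }
  nt <- Biostrings::DNAStringSet(res$nt)
  names(nt) <- res$orf_id
  aa <- translateSeq(res$nt, code)
  aa <- sub("\\*$", "", aa)
  aaSet <- Biostrings::AAStringSet(aa)
  names(aaSet) <- res$orf_id
  info <- res[, c("orf_id", "transcript_id", "frame", "start", "end",
                  "complete")]
  rownames(info) <- NULL
  OrfSet(info = info, ntSeq = nt, aaSeq = aaSet, codeId = codeId)
}

#' @rdname enumerateOrfs
#' @param transcripts,code,minLen,startCodons as in `enumerateOrfs`.
#' @export
enumeratePartialOrfs <- function(transcripts, code = geneticCode(1),
                                 minLen = 150L,
                                 startCodons = START_CODONS) {
  enumerateOrfs(transcripts, code, minLen, partial = TRUE,
                startCodons = startCodons)
}

# ORF spans (codon indices, inclusive of terminal stop) for one reading
# strand at one frame offset; returns NULL or list(from, to, complete)
frameOrfHits <- function(str, off, code, minLen, partial, startCodons) {
  cod <- frameCodons(str, off)
  n <- length(cod)
  if (n == 0L) return(NULL)
  aa <- unname(code[cod])          # NA for non-ACGT codons (never stop/start)
  stops <- which(!is.na(aa) & aa == "*")
  starts <- which(cod %in% startCodons)
  minCod <- minLen %/% 3L
  from <- integer(0); to <- integer(0); complete <- logical(0)
  if (length(stops)) {
    segStart <- c(1L, head(stops, -1L) + 1L)   # first codon of each segment
    # first start codon within each stop-bounded segment (before the stop)
    if (length(starts)) {
      seg <- findInterval(starts, stops) + 1L  # segment index per start codon
      ok <- seg <= length(stops) & starts < stops[pmin(seg, length(stops))]
      firstStart <- rep(NA_integer_, length(stops))
      if (any(ok)) {
        agg <- tapply(starts[ok], seg[ok], min)
        firstStart[as.integer(names(agg))] <- as.integer(agg)
      }
    } else firstStart <- rep(NA_integer_, length(stops))
    hasStart <- !is.na(firstStart)
    # complete: first start .. stop
    cf <- firstStart[hasStart]; ct <- stops[hasStart]
    keep <- (ct - cf + 1L) >= minCod
    from <- cf[keep]; to <- ct[keep]; complete <- rep(TRUE, sum(keep))
    if (partial && any(!hasStart)) {
      pf <- segStart[!hasStart]; pt <- stops[!hasStart]
      keep <- (pt - pf + 1L) >= minCod
      from <- c(from, pf[keep]); to <- c(to, pt[keep])
      complete <- c(complete, rep(FALSE, sum(keep)))
    }
  }
  if (partial) {
    # trailing stretch truncated by the transcript edge (no terminal stop)
    tf <- if (length(stops)) stops[length(stops)] + 1L else 1L
    if (tf <= n && (n - tf + 1L) >= minCod) {
      from <- c(from, tf); to <- c(to, n)
      complete <- c(complete, FALSE)
    }
  }
  if (!length(from)) return(NULL)
  ord <- order(from)
  list(from = from[ord], to = to[ord], complete = complete[ord])
}
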