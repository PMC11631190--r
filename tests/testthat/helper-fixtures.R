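# shared fixtures and independent oracles (built in code; no stored data)

randomTranscripts <- function(n, len, seed = 1, prefix = "t") {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      L <- if (length(len) == 2L) sample(len[1]:len[2], 1L) else len
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("%s%04d", prefix, seq_len(n))
    out
  })
}

# independent six-frame ORF oracle: full-frame translation via Biostrings,
# then regex segmentation of the protein string (complete ORFs are the
# leftmost M..* stretches between stops; partial segments lack the M or the
# stop). Shares no scanning code with the package implementation.
bruteForceOrfs <- function(transcripts, code = Biostrings::getGeneticCode("1"),
                           minLen = 150L, partial = FALSE) {
  rows <- list()
  rcSet <- Biostrings::reverseComplement(transcripts)
  widths <- Biostrings::width(transcripts)
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    strSet <- if (fr > 0L) transcripts else rcSet
    off <- abs(fr) - 1L
    nCod <- (widths - off) %/% 3L
    ok <- which(nCod >= 1L)
    if (!length(ok)) next
    aaSet <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::subseq(strSet[ok], off + 1L, off + 3L * nCod[ok]),
      genetic.code = code, if.fuzzy.codon = "X", no.init.codon = TRUE)))
    for (idx in seq_along(ok)) {
      tid <- names(transcripts)[ok[idx]]
      L <- widths[ok[idx]]
      aa <- aaSet[idx]
      from <- integer(0); to <- integer(0); complete <- logical(0)
      m <- gregexpr("M[^*]*\\*", aa)[[1]]
      if (m[1] != -1L) {
        from <- as.integer(m)
        to <- as.integer(m) + attr(m, "match.length") - 1L
        complete <- rep(TRUE, length(m))
      }
      if (partial) {
        # stop-bounded segments with no M at all (pad with a sentinel stop
        # so a zero-width lookbehind marks every segment boundary)
        segs <- gregexpr("(?<=\\*)[^*M]*\\*", paste0("*", aa),
                         perl = TRUE)[[1]]
        if (segs[1] != -1L) {
          from <- c(from, as.integer(segs) - 1L)
          to <- c(to, as.integer(segs) - 2L + attr(segs, "match.length"))
          complete <- c(complete, rep(FALSE, length(segs)))
        }
        # trailing stretch without a stop
        tail0 <- regexpr("[^*]+$", aa)
        if (tail0 != -1L) {
          from <- c(from, as.integer(tail0))
          to <- c(to, nchar(aa))
          complete <- c(complete, FALSE)
        }
      }
      keep <- (to - from + 1L) * 3L >= minLen
      if (!any(keep)) next
      from <- from[keep]; to <- to[keep]; complete <- complete[keep]
      rsStart <- off + 3L * (from - 1L) + 1L
      rsEnd <- off + 3L * to
      if (fr > 0L) { st <- rsStart; en <- rsEnd
      } else { st <- L - rsEnd + 1L; en <- L - rsStart + 1L }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tid, frame = fr, start = st, end = en,
        complete = complete, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      complete = logical(0)))
  out[order(out$transcript_id, out$frame, out$start), ]
}

canonicalOrfTable <- function(orfs) {
  info <- orfInfo(orfs)[, c("transcript_id", "frame", "start", "end",
                            "complete")]
  info <- info[order(info$transcript_id, info$frame, info$start), ]
  rownames(info) <- NULL
  info
}

# stride-3 codon-count oracle, independent of trinucleotideFrequency
codonCountOracle <- function(seqs) {
  vocab <- sort(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T"))[, 3:1], 1, paste,
                      collapse = ""))
  t(vapply(as.character(seqs), function(s) {
    n <- nchar(s) %/% 3L
    cod <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    tab <- table(factor(cod, levels = vocab))
    as.integer(tab)
  }, integer(64L)))
}

# nearest-centroid classifier on codon frequencies (independent oracle)
centroidAccuracy <- function(Xtr, ytr, Xte, yte) {
  f <- function(M) M / pmax(rowSums(M), 1)
  Xtr <- f(Xtr); Xte <- f(Xte)
  cents <- do.call(rbind, lapply(sort(unique(ytr)), function(cl)
    colMeans(Xtr[ytr == cl, , drop = FALSE])))
  rownames(cents) <- sort(unique(ytr))
  d <- outer(rowSums(Xte^2), rowSums(cents^2), "+") - 2 * Xte %*% t(cents)
  mean(rownames(cents)[apply(d, 1, which.min)] == yte)
}

# two standard distinct-fingerprint taxa used across classification tests
distinctTaxa <- function(seedA = 101, seedB = 202) {
  list(makeTaxonModel("taxA", gc3Target = 30, divergence = 1, seed = seedA),
       makeTaxonModel("taxB", gc3Target = 80, divergence = 1, seed = seedB))
}

predLabels <- function(probs) colnames(probs)[max.col(probs, ties.method = "first")]
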