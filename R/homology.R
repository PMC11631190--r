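#' Translated-search parameters
#'
#' Defaults mirror the production translated-search call (`-e 1e-30 -k 1`):
#' report at most one hit per transcript, at an e-value at or below 1e-30.
#'
#' @param evalueCut e-value threshold (> 0).
#' @param maxHitsPerQuery maximum reported hits per transcript (>= 1).
#' @return validated parameter list.
#' @export
searchParams <- function(evalueCut = 1e-30, maxHitsPerQuery = 1L) {
  stopifnot(evalueCut > 0, maxHitsPerQuery >= 1L)
  list(evalueCut = evalueCut, maxHitsPerQuery = as.integer(maxHitsPerQuery))
}

# Karlin-Altschul parameters for gapped BLOSUM62 (11/1 gaps)
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Translated homology search of transcripts against a reference proteome
#'
#' Finds, per transcript, the reading frame and region coding for a protein
#' in the reference database. The internal backend translates each
#' transcript in all six frames, seeds candidate pairs on shared exact 5-mer
#' amino-acid words, extends seeds with a BLOSUM62 local alignment, keeps
#' alignments with identity >= 60% over >= 50 aligned residues, converts
#' scores to bits with Karlin-Altschul statistics (an exact 50-aa match
#' always passes the default e-value cut), and reports the best
#' `maxHitsPerQuery` hits per transcript. The `"diamond"` backend shells out
#' to DIAMOND blastx when available.
#'
#' @param transcripts named `DNAStringSet` (nucleotide).
#' @param proteinDb named `AAStringSet` (reference proteome).
#' @param params from [searchParams()].
#' @param backend `"internal"` or `"diamond"`.
#' @param seedLen exact amino-acid word size for seeding (internal backend).
#' @param minSeeds minimum shared distinct words to trigger alignment of a
#'   pair (default 8; an exact 50-aa match shares ~46).
#' @return data.frame with columns `qid`, `sid`, `qlen` (nt), `slen` (aa),
#'   `aln_len`, `pident`, `qframe`, `qstart`, `qend` (1-based forward-strand
#'   nt coordinates of the aligned region), `qcov`, `scov`, `bits`, `evalue`.
#' @export
runReferenceSearch <- function(transcripts, proteinDb,
                               params = searchParams(),
                               backend = c("internal", "diamond"),
                               seedLen = 5L, minSeeds = 8L) {
  backend <- match.arg(backend)
  if (length(proteinDb) == 0L) stop("reference proteome is empty")
  if (backend == "diamond") {
    if (Sys.which("diamond") == "")
      stop("search backend 'diamond' requested but the diamond program ",
           "was not found on the PATH")
    return(runDiamondSearch(transcripts, proteinDb, params))
  }
  dbChr <- as.character(proteinDb)
  dbLen <- nchar(dbChr)
  idx <- buildWordIndex(dbChr, seedLen)
  totalDbLen <- sum(dbLen)
  out <- vector("list", length(transcripts))
  txChr <- as.character(transcripts)
  for (t in seq_along(transcripts)) {
    s <- txChr[[t]]
    L <- nchar(s)
    rc <- revcompChr(s)
    hits <- list()
    for (fr in 1:6) {
      strand <- if (fr <= 3L) 1L else -1L
      off <- (fr - 1L) %% 3L
      str <- if (strand == 1L) s else rc
      n <- (L - off) %/% 3L
      if (n < 50L) next
      aaSeq <- translateFrame(str, off, n)
      cands <- seedCandidates(aaSeq, idx, seedLen, minSeeds)
      for (ci in cands) {
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(aaSeq), Biostrings::AAString(dbChr[[ci]]),
          type = "local", substitutionMatrix = "BLOSUM62",
          gapOpening = 11, gapExtension = 1)
        alnLen <- Biostrings::nchar(aln)
        if (alnLen < 50L) next
        pid <- 100 * Biostrings::nmatch(aln) / alnLen
        if (pid < 60) next
        bits <- (KA_LAMBDA * Biostrings::score(aln) - log(KA_K)) / log(2)
        evalue <- (L / 3) * totalDbLen * 2^(-bits)
        if (evalue > params$evalueCut) next
        pr <- Biostrings::pattern(aln)
        sr <- Biostrings::subject(aln)
        aaFrom <- Biostrings::start(pr)
        aaTo <- Biostrings::end(pr)
        # aligned region in forward-strand nt coordinates
        rsStart <- off + 3L * (aaFrom - 1L) + 1L   # on reading strand
        rsEnd <- off + 3L * aaTo
        if (strand == 1L) { qs <- rsStart; qe <- rsEnd
        } else { qs <- L - rsEnd + 1L; qe <- L - rsStart + 1L }
        hits[[length(hits) + 1L]] <- data.frame(
          qid = names(transcripts)[t], sid = names(proteinDb)[ci],
          qlen = L, slen = dbLen[ci], aln_len = alnLen, pident = pid,
          qframe = strand * (off + 1L), qstart = qs, qend = qe,
          qcov = (aaTo - aaFrom + 1L) * 3 / L,
          scov = (Biostrings::end(sr) - Biostrings::start(sr) + 1L) /
            dbLen[ci],
          bits = bits, evalue = evalue, stringsAsFactors = FALSE)
      }
    }
    if (!length(hits)) next
    hits <- do.call(rbind, hits)
    hits <- hits[order(-hits$bits, hits$evalue, hits$sid), , drop = FALSE]
    out[[t]] <- head(hits, params$maxHitsPerQuery)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(qid = character(0), sid = character(0),
                      qlen = integer(0), slen = integer(0),
                      aln_len = integer(0), pident = numeric(0),
                      qframe = integer(0), qstart = integer(0),
                      qend = integer(0), qcov = numeric(0), scov = numeric(0),
                      bits = numeric(0), evalue = numeric(0))
  rownames(out) <- NULL
  out
}

translateFrame <- function(str, off, n) {
  cod <- substring(str, off + 3L * seq_len(n) - 2L, off + 3L * seq_len(n))
  aa <- unname(GENCODE1[cod])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# db word index: environment mapping aa 5-mer -> integer protein ids
buildWordIndex <- function(dbChr, seedLen) {
  env <- new.env(hash = TRUE, size = 4L * sum(nchar(dbChr)))
  for (i in seq_along(dbChr)) {
    L <- nchar(dbChr[[i]])
    if (L < seedLen) next
    words <- unique(substring(dbChr[[i]], seq_len(L - seedLen + 1L),
                              seedLen:L))
    for (w in words) {
      prev <- if (exists(w, envir = env, inherits = FALSE))
        get(w, envir = env) else integer(0)
      assign(w, c(prev, i), envir = env)
    }
  }
  env
}

# candidate db proteins sharing >= minSeeds distinct words with the query
# frame, best-seeded first (capped to bound alignment work; a true coding
# region shares most of its words with its protein, while compositional
# bias alone rarely yields more than a handful)
seedCandidates <- function(aaSeq, idx, seedLen, minSeeds) {
  L <- nchar(aaSeq)
  if (L < seedLen) return(integer(0))
  words <- unique(substring(aaSeq, seq_len(L - seedLen + 1L), seedLen:L))
  hits <- unlist(lapply(words, function(w) {
    if (exists(w, envir = idx, inherits = FALSE))
      get(w, envir = idx) else NULL
  }))
  if (is.null(hits)) return(integer(0))
  tab <- table(hits)
  tab <- tab[tab >= minSeeds]
  if (!length(tab)) return(integer(0))
  ids <- as.integer(names(tab))
  head(ids[order(-as.integer(tab), ids)], 3L)
}

runDiamondSearch <- function(transcripts, proteinDb, params) {
  qf <- tempfile(fileext = ".fasta"); df <- tempfile(fileext = ".fasta")
  dbf <- tempfile(); outf <- tempfile()
  on.exit(unlink(c(qf, df, dbf, outf, paste0(dbf, ".dmnd"))), add = TRUE)
  writeFasta(transcripts, qf); writeFasta(proteinDb, df)
  system2("diamond", c("makedb", "--in", df, "-d", dbf), stdout = FALSE)
  system2("diamond",
          c("blastx", "-q", qf, "-d", dbf, "-o", outf, "--very-sensitive",
            "-k", params$maxHitsPerQuery, "-e", format(params$evalueCut),
            "-f", "6", "qseqid", "sseqid", "qlen", "slen", "length",
            "pident", "qframe", "qstart", "qend", "bitscore", "evalue"),
          stdout = FALSE)
  tab <- read.table(outf, sep = "\t", stringsAsFactors = FALSE)
  names(tab) <- c("qid", "sid", "qlen", "slen", "aln_len", "pident",
                  "qframe", "qstart", "qend", "bits", "evalue")
  tab$qstart2 <- pmin(tab$qstart, tab$qend)
  tab$qend <- pmax(tab$qstart, tab$qend)
  tab$qstart <- tab$qstart2; tab$qstart2 <- NULL
  tab$qcov <- tab$aln_len * 3 / tab$qlen
  tab$scov <- tab$aln_len / tab$slen
  tab
}

#' Persist alignment hits as TSV
#'
#' Mirrors the 7-column tabular layout
#' `qseqid sseqid qlen slen length pident qframe`.
#'
#' @param hits data.frame from [runReferenceSearch()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHits <- function(hits, path) {
  tab <- hits[, c("qid", "sid", "qlen", "slen", "aln_len", "pident",
                  "qframe")]
  names(tab) <- c("qseqid", "sseqid", "qlen", "slen", "length", "pident",
                  "qframe")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the ORF-prediction training set from reference hits
#'
#' Each hit contributes one in-frame positive: the aligned transcript region
#' read in the hit's frame, trimmed to a codon multiple. Each positive is
#' paired with one out-of-frame negative: the same transcript span re-read
#' in one of the five non-coding orientations (+2/+3 shifts of the reading
#' strand, or any frame of the opposite strand), drawn uniformly with the
#' given seed and trimmed to a codon multiple. Pairs whose region is shorter
#' than `minLen` are skipped and counted.
#'
#' @param hits data.frame from [runReferenceSearch()].
#' @param transcripts the searched `DNAStringSet`.
#' @param seed integer seed for the orientation draw.
#' @param minLen minimum usable region length, nt (default 150).
#' @return list with `positives` and `negatives` (named `DNAStringSet`s of
#'   equal length), `labels` (factor, `"in-frame"` / `"out-of-frame"` in
#'   positive/negative order), `skipped` (count), and `seed`.
#' @export
buildTrainingSet <- function(hits, transcripts, seed = 1L, minLen = 150L) {
  stopifnot(all(hits$qid %in% names(transcripts)))
  txChr <- as.character(transcripts)
  pos <- character(0); neg <- character(0); ids <- character(0)
  skipped <- 0L
  orientations <- c("+2", "+3", "-1", "-2", "-3")
  draws <- withSeed(seed, sample(orientations, nrow(hits), replace = TRUE))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    region <- substring(txChr[[h$qid]], h$qstart, h$qend)
    if (h$qframe < 0L) region <- revcompChr(region)
    region <- trimCodon(region)
    if (nchar(region) < minLen) { skipped <- skipped + 1L; next }
    pos <- c(pos, region)
    neg <- c(neg, reorient(region, draws[i]))
    ids <- c(ids, h$qid)
  }
  if (skipped > 0L)
    message(skipped, " hit region(s) shorter than ", minLen,
            " nt skipped from the training set")
  positives <- Biostrings::DNAStringSet(pos)
  negatives <- Biostrings::DNAStringSet(neg)
  if (length(pos)) {
    names(positives) <- paste0(ids, ".pos")
    names(negatives) <- paste0(ids, ".neg")
  }
  list(positives = positives, negatives = negatives,
       labels = factor(rep(c("in-frame", "out-of-frame"),
                           c(length(pos), length(neg))),
                       levels = c("in-frame", "out-of-frame")),
       skipped = skipped, seed = as.integer(seed))
}

trimCodon <- function(s) {
  n <- nchar(s) - nchar(s) %% 3L
  substring(s, 1L, n)
}

# re-read an in-frame sequence in a non-coding orientation
reorient <- function(s, orientation) {
  out <- switch(orientation,
    "+2" = substring(s, 2L, nchar(s)),
    "+3" = substring(s, 3L, nchar(s)),
    "-1" = revcompChr(s),
    "-2" = substring(revcompChr(s), 2L),
    "-3" = substring(revcompChr(s), 3L))
  trimCodon(out)
}
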