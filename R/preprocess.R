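#' Remove short transcripts
#'
#' First-stage length filter for assembled transcripts. Order is preserved.
#'
#' @param transcripts named `DNAStringSet`.
#' @param minLen minimum transcript length in nucleotides (default 300).
#' @return the transcripts with width >= `minLen`.
#' @export
filterByLength <- function(transcripts, minLen = 300L) {
  stopifnot(minLen >= 0)
  transcripts[Biostrings::width(transcripts) >= minLen]
}

#' Screen transcripts for rRNA by-catch
#'
#' Flags transcripts that look like ribosomal RNA. The internal backend
#' counts the fraction of a transcript's 31-mers (either strand) present in a
#' user-supplied rRNA reference FASTA and flags the transcript when that
#' fraction reaches `minFrac`; k-mers containing non-ACGT characters never
#' match. The `"barrnap"` backend shells out to Barrnap over all four kingdom
#' models and requires the program on the PATH.
#'
#' @param transcripts named `DNAStringSet`.
#' @param rrnaRef rRNA reference: a `DNAStringSet` or FASTA path (internal
#'   backend).
#' @param backend `"internal"` or `"barrnap"`.
#' @param k k-mer size for the internal screen (default 31).
#' @param minFrac flagging threshold on the shared-k-mer fraction
#'   (default 0.25).
#' @return list with elements `kept` and `flagged`, two `DNAStringSet`s that
#'   partition the input.
#' @export
screenRrna <- function(transcripts, rrnaRef = NULL,
                       backend = c("internal", "barrnap"),
                       k = 31L, minFrac = 0.25) {
  backend <- match.arg(backend)
  if (backend == "barrnap") {
    if (Sys.which("barrnap") == "")
      stop("rRNA backend 'barrnap' requested but the barrnap program ",
           "was not found on the PATH")
    return(screenRrnaBarrnap(transcripts))
  }
  if (is.null(rrnaRef))
    stop("internal rRNA screen requires an rRNA reference ",
         "(DNAStringSet or FASTA path)")
  if (is.character(rrnaRef)) rrnaRef <- readTranscripts(rrnaRef)
  refKmers <- unique(unlist(lapply(
    as.character(rrnaRef),
    function(s) c(seqKmers(s, k), seqKmers(revcompChr(s), k)))))
  refEnv <- new.env(hash = TRUE, size = max(length(refKmers), 1L))
  for (w in refKmers) assign(w, TRUE, envir = refEnv)
  frac <- vapply(as.character(transcripts), function(s) {
    km <- seqKmers(s, k)
    if (!length(km)) return(0)
    mean(vapply(km, exists, logical(1), envir = refEnv, inherits = FALSE))
  }, numeric(1), USE.NAMES = FALSE)
  isRrna <- frac >= minFrac
  list(kept = transcripts[!isRrna], flagged = transcripts[isRrna])
}

# k-mers of a sequence, excluding any containing a non-ACGT character
seqKmers <- function(seq, k, stride = 1L) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq.int(1L, L - k + 1L, by = stride)
  km <- substring(seq, starts, starts + k - 1L)
  km[!grepl("[^ACGT]", km)]
}

screenRrnaBarrnap <- function(transcripts) {
  fa <- tempfile(fileext = ".fasta")
  on.exit(unlink(fa), add = TRUE)
  writeFasta(transcripts, fa)
  flaggedIds <- character(0)
  for (kingdom in c("bac", "arc", "mito", "euk")) {
    out <- suppressWarnings(system2("barrnap",
      c("--kingdom", kingdom, fa), stdout = TRUE, stderr = FALSE))
    hits <- out[!startsWith(out, "#")]
    if (length(hits))
      flaggedIds <- c(flaggedIds, vapply(strsplit(hits, "\t"), `[`,
                                         character(1), 1L))
  }
  isRrna <- names(transcripts) %in% flaggedIds
  list(kept = transcripts[!isRrna], flagged = transcripts[isRrna])
}

#' Clustering parameters for isoform collapse
#'
#' Defaults mirror the CD-HIT-EST invocation
#' `cd-hit -G 0 -c 0.97 -aS 1.0 -aL 0.005`: local identity 0.97, full
#' coverage of the shorter sequence, and at least 0.5% coverage of the
#' longer.
#'
#' @param identity minimum local identity, fraction in (0, 1].
#' @param shortCov minimum aligned coverage of the shorter sequence.
#' @param longCov minimum aligned coverage of the longer sequence.
#' @return a list of validated parameters.
#' @export
clusteringParams <- function(identity = 0.97, shortCov = 1.0,
                             longCov = 0.005) {
  stopifnot(identity > 0, identity <= 1,
            shortCov > 0, shortCov <= 1,
            longCov >= 0, longCov <= 1)
  list(identity = identity, shortCov = shortCov, longCov = longCov)
}

#' Collapse redundant isoforms by greedy clustering
#'
#' Greedy longest-first clustering in the CD-HIT-EST style: sequences are
#' visited longest first (ties broken lexicographically by id); a sequence
#' joins the first existing cluster whose representative aligns to it at
#' local identity >= `params$identity` with the alignment covering
#' >= `params$shortCov` of the shorter and >= `params$longCov` of the longer
#' sequence (either strand); otherwise it founds a new cluster. Each
#' cluster's representative is its longest member. A shared-k-mer prefilter
#' skips alignment of obviously unrelated pairs.
#'
#' @param transcripts named `DNAStringSet`.
#' @param params from [clusteringParams()].
#' @param prefilterK word size for the candidate prefilter (default 20).
#' @param minShared minimum shared prefilter words before a representative
#'   is aligned against (default 3; near-identical isoforms share hundreds).
#' @return list with `representatives` (a `DNAStringSet`) and `clusterMap`
#'   (data.frame: `member_id`, `representative_id`; every id maps, each
#'   representative to itself).
#' @export
clusterIsoforms <- function(transcripts, params = clusteringParams(),
                            prefilterK = 20L, minShared = 3L) {
  stopifnot(length(transcripts) > 0L)
  ids <- names(transcripts)
  w <- Biostrings::width(transcripts)
  ord <- order(-w, ids)
  repIds <- character(0)
  repSeqs <- character(0)
  repKmerEnv <- new.env(hash = TRUE)
  assignment <- character(length(transcripts))
  names(assignment) <- ids
  for (i in ord) {
    id <- ids[i]
    s <- as.character(transcripts[[i]])
    rc <- revcompChr(s)
    # representatives are indexed at stride 4, queried at stride 1, so a
    # contained near-identical sequence still shares many words
    km <- unique(c(seqKmers(s, prefilterK), seqKmers(rc, prefilterK)))
    hits <- unlist(lapply(km, function(x) {
      if (exists(x, envir = repKmerEnv, inherits = FALSE))
        get(x, envir = repKmerEnv) else NULL
    }))
    cand <- character(0)
    if (!is.null(hits) && length(hits)) {
      tab <- table(hits)
      tab <- tab[tab >= minShared]
      cand <- names(tab)[order(-as.integer(tab), names(tab))]
      cand <- head(cand, 5L)
    }
    placed <- NA_character_
    for (j in cand) {
      if (seqMatchesRep(s, rc, repSeqs[[j]], params)) { placed <- j; break }
    }
    if (is.na(placed)) {
      repIds <- c(repIds, id)
      repSeqs[[id]] <- s
      for (x in unique(seqKmers(s, prefilterK, stride = 4L))) {
        prev <- if (exists(x, envir = repKmerEnv, inherits = FALSE))
          get(x, envir = repKmerEnv) else character(0)
        assign(x, c(prev, id), envir = repKmerEnv)
      }
      assignment[id] <- id
    } else {
      assignment[id] <- placed
    }
  }
  list(representatives = transcripts[repIds],
       clusterMap = data.frame(member_id = ids,
                               representative_id = unname(assignment[ids]),
                               stringsAsFactors = FALSE))
}

# does candidate sequence s (or its revcomp) cluster with representative?
# representative is at least as long by construction of the greedy order
seqMatchesRep <- function(s, rc, repSeq, params) {
  for (qry in c(s, rc)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qry), Biostrings::DNAString(repSeq),
      type = "local")
    alnLen <- Biostrings::nchar(aln)
    if (alnLen == 0L) next
    ident <- Biostrings::nmatch(aln) / alnLen
    covShort <- alnLen / min(nchar(qry), nchar(repSeq))
    covLong <- alnLen / max(nchar(qry), nchar(repSeq))
    if (ident >= params$identity && covShort >= params$shortCov &&
        covLong >= params$longCov)
      return(TRUE)
  }
  FALSE
}

#' Write a cluster map as TSV
#'
#' @param clusterMap data.frame from [clusterIsoforms()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeClusterMap <- function(clusterMap, path) {
  write.table(clusterMap, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
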