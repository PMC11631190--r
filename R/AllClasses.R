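#' OrfSet: a set of putative ORFs with coordinates and sequences
#'
#' Container for putative ORFs (pORFs) called from a transcript set. Each ORF
#' carries its transcript of origin, reading frame (+1..+3 forward, -1..-3
#' reverse), 1-based inclusive coordinates on the forward strand of the
#' transcript, a completeness flag (start codon and in-frame stop present),
#' the nucleotide sequence in reading orientation (terminal stop included for
#' complete ORFs) and its translation (terminal stop excluded).
#'
#' @slot info data.frame with columns `orf_id`, `transcript_id`, `frame`,
#'   `start`, `end`, `complete`.
#' @slot ntSeq `DNAStringSet` of ORF nucleotide sequences, named by `orf_id`.
#' @slot aaSeq `AAStringSet` of translations, named by `orf_id`.
#' @slot codeId NCBI translation-table id used for translation.
#' @export
setClass("OrfSet",
  representation(info = "data.frame",
                 ntSeq = "ANY",
                 aaSeq = "ANY",
                 codeId = "character"))

setValidity("OrfSet", function(object) {
  info <- object@info
  need <- c("orf_id", "transcript_id", "frame", "start", "end", "complete")
  if (!all(need %in% names(info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (nrow(info) != length(object@ntSeq) || nrow(info) != length(object@aaSeq))
    return("info rows and sequence counts differ")
  if (nrow(info) == 0L) return(TRUE)
  if (anyDuplicated(info$orf_id)) return("duplicate orf_id")
  if (!identical(names(object@ntSeq), info$orf_id) ||
      !identical(names(object@aaSeq), info$orf_id))
    return("sequence names must match info$orf_id")
  len <- info$end - info$start + 1L
  if (any(len %% 3L != 0L)) return("ORF span not a codon multiple")
  if (any(len != Biostrings::width(object@ntSeq)))
    return("nt_seq length differs from coordinate span")
  if (!all(info$frame %in% c(1L, 2L, 3L, -1L, -2L, -3L)))
    return("frame must be in {+1,+2,+3,-1,-2,-3}")
  TRUE
})

OrfSet <- function(info, ntSeq, aaSeq, codeId = "1") {
  new("OrfSet", info = info, ntSeq = ntSeq, aaSeq = aaSeq,
      codeId = as.character(codeId))
}

#' @describeIn OrfSet number of ORFs
#' @param x,object an `OrfSet`.
#' @export
setMethod("length", "OrfSet", function(x) nrow(x@info))

setMethod("show", "OrfSet", function(object) {
  info <- object@info
  cat("OrfSet with", nrow(info), "ORFs on",
      length(unique(info$transcript_id)), "transcripts",
      sprintf("(genetic code %s)\n", object@codeId))
  if (nrow(info)) {
    cat(sprintf("  complete: %d  partial: %d  median length: %d nt\n",
                sum(info$complete), sum(!info$complete),
                as.integer(stats::median(info$end - info$start + 1L))))
  }
})

#' Accessors for OrfSet
#'
#' @param x an `OrfSet`.
#' @return `orfInfo` the coordinate/flag data.frame; `ntSeqs` the
#'   `DNAStringSet`; `aaSeqs` the `AAStringSet`; `orfCode` the genetic-code id.
#' @export
orfInfo <- function(x) x@info

#' @rdname orfInfo
#' @export
ntSeqs <- function(x) x@ntSeq

#' @rdname orfInfo
#' @export
aaSeqs <- function(x) x@aaSeq

#' @rdname orfInfo
#' @export
orfCode <- function(x) x@codeId

# subset an OrfSet by logical/integer index
subsetOrfSet <- function(x, i) {
  info <- x@info[i, , drop = FALSE]
  rownames(info) <- NULL
  new("OrfSet", info = info, ntSeq = x@ntSeq[i], aaSeq = x@aaSeq[i],
      codeId = x@codeId)
}

#' CodonClassifier: a trained RBF support vector classifier on codon counts
#'
#' Holds everything needed to reproduce predictions without refitting: the
#' class labels, the fixed 64-codon vocabulary, the RBF kernel parameters,
#' per-class-pair support vectors with dual coefficients and intercepts, the
#' Platt sigmoid calibration for each pair, and provenance (genetic-code
#' table, seed, training-set hash, package version). Multiclass probabilities
#' come from pairwise coupling of the calibrated pair probabilities, so a
#' saved model reproduces bit-identical predictions when reloaded.
#'
#' @slot classes ordered class labels.
#' @slot vocabulary the fixed 64-codon feature order.
#' @slot pairs list of per-class-pair fits (`pos`, `neg`, `SV`, `coefs`,
#'   `rho`, `probA`, `probB`).
#' @slot gamma RBF kernel width.
#' @slot cost selected soft-margin cost C.
#' @slot cvTable data.frame of the C search (candidate C, mean CV accuracy).
#' @slot codeId genetic-code table id the training ORFs were called under.
#' @slot seed integer seed used for CV folds and calibration.
#' @slot trainingHash md5 of the training data.
#' @slot version package version that trained the model.
#' @export
setClass("CodonClassifier",
  representation(classes = "character", vocabulary = "character",
                 pairs = "list", gamma = "numeric", cost = "numeric",
                 cvTable = "data.frame", codeId = "character",
                 seed = "integer", trainingHash = "character",
                 version = "character"))

setValidity("CodonClassifier", function(object) {
  if (length(object@classes) < 2L) return("need >= 2 classes")
  if (length(object@vocabulary) != 64L) return("vocabulary must have 64 codons")
  k <- length(object@classes)
  if (length(object@pairs) != k * (k - 1L) / 2L)
    return("need one fit per class pair")
  TRUE
})

setMethod("show", "CodonClassifier", function(object) {
  cat("CodonClassifier (RBF SVC on in-frame codon counts)\n")
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
  cat(sprintf("  C = %.4g, gamma = %.4g, genetic code %s, seed %d\n",
              object@cost, object@gamma, object@codeId, object@seed))
  cat(sprintf("  support vectors: %d across %d class pair(s)\n",
              sum(vapply(object@pairs, function(p) nrow(p$SV), integer(1))),
              length(object@pairs)))
})

#' Accessors for CodonClassifier
#'
#' @param x a `CodonClassifier`.
#' @return `modelClasses` the ordered labels; `modelVocabulary` the codon
#'   order; `modelCode` the genetic-code id; `modelSeed` the training seed.
#' @export
modelClasses <- function(x) x@classes

#' @rdname modelClasses
#' @export
modelVocabulary <- function(x) x@vocabulary

#' @rdname modelClasses
#' @export
modelCode <- function(x) x@codeId

#' @rdname modelClasses
#' @export
modelSeed <- function(x) x@seed

#' TaxonModel: a codon-usage fingerprint for simulation
#'
#' A taxon is modelled by a probability vector over the 64 codons (stop
#' codons carry zero mass except as CDS terminators), constructed so that the
#' expected third-position GC of sampled codons equals `gc3Target`.
#'
#' @slot name taxon label.
#' @slot codonUsage named 64-simplex over codons.
#' @slot gc3Target target third-position GC, percent.
#' @slot utrBaseFreqs named 4-simplex over A,C,G,T for untranslated regions.
#' @slot seed integer seed the model was drawn with.
#' @export
setClass("TaxonModel",
  representation(name = "character", codonUsage = "numeric",
                 gc3Target = "numeric", utrBaseFreqs = "numeric",
                 seed = "integer"))

setValidity("TaxonModel", function(object) {
  u <- object@codonUsage
  if (length(u) != 64L || !identical(names(u), CODON_VOCABULARY))
    return("codonUsage must cover the 64-codon vocabulary in order")
  if (abs(sum(u) - 1) > 1e-8) return("codonUsage must sum to 1")
  if (any(u < 0)) return("codonUsage must be non-negative")
  if (object@gc3Target < 0 || object@gc3Target > 100)
    return("gc3Target must be in [0, 100]")
  TRUE
})

setMethod("show", "TaxonModel", function(object) {
  cat(sprintf("TaxonModel '%s': GC3 target %.1f%%, seed %d\n",
              object@name, object@gc3Target, object@seed))
})
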