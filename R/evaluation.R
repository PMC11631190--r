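#' Categorize predicted ORFs against best reference hits
#'
#' Applies the coverage-based quality categories to best-hit alignments of
#' predicted ORFs against a reference proteome:
#' \itemize{
#'   \item `no_hit`: the ORF found no reference hit;
#'   \item `out_of_frame`: the hit's frame on the ORF's own reading is not
#'     +1 (the ORF was called in the wrong orientation);
#'   \item `full_length`: in frame, the ORF is complete, and the alignment
#'     covers >= 98\% of both the ORF and the reference protein;
#'   \item `useful`: in frame, >= 98\% of the ORF aligned over >= 66\% of
#'     the reference protein;
#'   \item `in_frame_other`: any remaining in-frame hit.
#' }
#'
#' @param orfs an [OrfSet-class] of predictions.
#' @param hits data.frame from [runReferenceSearch()] run on the ORF
#'   nucleotide sequences (best hit only); `qid` must be orf ids.
#' @return data.frame: `orf_id`, `sid` (reference hit or `NA`), `category`.
#' @export
categorizePredictions <- function(orfs, hits) {
  info <- orfInfo(orfs)
  m <- match(info$orf_id, hits$qid)
  category <- rep("no_hit", nrow(info))
  sid <- rep(NA_character_, nrow(info))
  hit <- !is.na(m)
  h <- hits[m[hit], , drop = FALSE]
  sid[hit] <- h$sid
  inFrame <- h$qframe == 1L
  full <- inFrame & h$qcov >= 0.98 & h$scov >= 0.98 & info$complete[hit]
  useful <- inFrame & !full & h$qcov >= 0.98 & h$scov >= 0.66
  cat_h <- ifelse(!inFrame, "out_of_frame",
                  ifelse(full, "full_length",
                         ifelse(useful, "useful", "in_frame_other")))
  category[hit] <- cat_h
  data.frame(orf_id = info$orf_id, sid = sid, category = category,
             stringsAsFactors = FALSE)
}

#' Precision, recall and F1 against a truth table
#'
#' Scores predicted labels against true labels per class: precision =
#' TP/(TP+FP), recall = TP/(TP+FN), F1 = harmonic mean of the two, and
#' macro-F1 = unweighted mean of per-class F1. Ids listed in `trainingIds`
#' are excluded from scoring (annotated training sequences are never
#' evaluated). A zero denominator yields 0 with a warning.
#'
#' @param predicted named character vector: id -> predicted label.
#' @param truth named character vector: id -> true label (the classes
#'   scored are the truth's classes).
#' @param trainingIds ids to exclude from scoring.
#' @return list: `perClass` (data.frame with `class`, `TP`, `FP`, `FN`,
#'   `precision`, `recall`, `f1`), `macroF1`, `accuracy`, `confusion`
#'   (table, truth in rows).
#' @examples
#' scorePredictions(c(a = "x", b = "x", c = "y"),
#'                  c(a = "x", b = "y", c = "y"))$macroF1
#' @export
scorePredictions <- function(predicted, truth, trainingIds = NULL) {
  if (!length(truth)) stop("empty truth table")
  keep <- setdiff(intersect(names(predicted), names(truth)), trainingIds)
  if (!length(keep)) stop("no scorable ids after training exclusion")
  pred <- as.character(predicted[keep])
  tru <- as.character(truth[keep])
  classes <- sort(unique(tru))
  confusion <- table(truth = factor(tru, levels = classes),
                     predicted = factor(pred,
                                        levels = union(classes,
                                                       unique(pred))))
  perClass <- do.call(rbind, lapply(classes, function(cl) {
    TP <- sum(pred == cl & tru == cl)
    FP <- sum(pred == cl & tru != cl)
    FN <- sum(pred != cl & tru == cl)
    data.frame(class = cl, TP = TP, FP = FP, FN = FN,
               precision = safeRatio(TP, TP + FP, "precision", cl),
               recall = safeRatio(TP, TP + FN, "recall", cl),
               stringsAsFactors = FALSE)
  }))
  perClass$f1 <- ifelse(perClass$precision + perClass$recall > 0,
                        2 * perClass$precision * perClass$recall /
                          (perClass$precision + perClass$recall), 0)
  list(perClass = perClass, macroF1 = mean(perClass$f1),
       accuracy = mean(pred == tru), confusion = confusion)
}

safeRatio <- function(num, den, what, cl) {
  if (den == 0) {
    warning("zero denominator for ", what, " of class '", cl,
            "'; reporting 0")
    return(0)
  }
  num / den
}

#' Count unique reference loci recovered
#'
#' Number of distinct reference-protein ids hit by any correctly framed
#' prediction.
#'
#' @param categories data.frame from [categorizePredictions()].
#' @return integer count.
#' @export
uniqueLoci <- function(categories) {
  ok <- !(categories$category %in% c("no_hit", "out_of_frame"))
  length(unique(categories$sid[ok]))
}
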