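#' Load and validate a user class table
#'
#' Reads the two-column TSV of user-classified training ORFs
#' (`orf_id<TAB>label`). A header line is optional and `#` comment lines are
#' ignored; labels are free strings. The table must name at least two
#' distinct classes, reference only ids present in the query set, and not
#' assign conflicting labels to the same id (exact duplicate rows are
#' collapsed).
#'
#' @param path TSV path, or a data.frame with two columns.
#' @param orfIds character vector of valid ORF ids (the query FASTA's ids).
#' @return data.frame with columns `orf_id`, `label`; attribute `source`
#'   set to `"user"`.
#' @export
loadClassTable <- function(path, orfIds) {
  if (is.character(path)) {
    tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE, quote = "",
                      col.names = c("orf_id", "label"))
    # tolerate an optional header line
    if (nrow(tab) && tab$orf_id[1] %in% c("orf_id", "id") &&
        !(tab$orf_id[1] %in% orfIds))
      tab <- tab[-1, , drop = FALSE]
  } else {
    tab <- as.data.frame(path)[, 1:2]
    names(tab) <- c("orf_id", "label")
  }
  tab <- unique(tab)
  dup <- tab$orf_id[duplicated(tab$orf_id)]
  if (length(dup))
    stop("conflicting labels for orf id(s): ",
         paste(unique(dup), collapse = ", "))
  unknown <- setdiff(tab$orf_id, orfIds)
  if (length(unknown))
    stop("class table names id(s) absent from the query set: ",
         paste(head(unknown, 10L), collapse = ", "))
  if (length(unique(tab$label)) < 2L)
    stop("need >= 2 classes in the training table (got ",
         length(unique(tab$label)), ")")
  rownames(tab) <- NULL
  attr(tab, "source") <- "user"
  tab
}

#' Build a class table from external taxonomic-classifier labels
#'
#' Converts raw per-sequence category calls from an external taxonomic
#' classifier (e.g. eukaryotic / bacterial / archaeal / viruses) into a
#' training table by drawing a seeded random sample of up to `cap`
#' (default 100) ids per category; categories with fewer than `floor`
#' (default 25) available ids are dropped with a warning.
#'
#' @param rawLabels named character vector: id -> category.
#' @param cap maximum training sequences per category.
#' @param floor minimum available ids for a category to be used.
#' @param seed integer seed for the sampling.
#' @return data.frame (`orf_id`, `label`) with attribute `source` set to
#'   `"external_classifier"`.
#' @export
externalClassifierLabels <- function(rawLabels, cap = 100L, floor = 25L,
                                     seed = 1L) {
  stopifnot(!is.null(names(rawLabels)))
  byCat <- split(names(rawLabels), as.character(rawLabels))
  small <- names(byCat)[lengths(byCat) < floor]
  if (length(small)) {
    warning("category(ies) with fewer than ", floor,
            " sequences dropped: ", paste(small, collapse = ", "))
    byCat <- byCat[lengths(byCat) >= floor]
  }
  if (length(byCat) < 2L)
    stop("fewer than 2 categories with >= ", floor,
         " sequences; cannot build a training table")
  tab <- withSeed(seed, {
    do.call(rbind, lapply(names(byCat), function(cat) {
      ids <- sort(byCat[[cat]])
      data.frame(orf_id = sample(ids, min(cap, length(ids))),
                 label = cat, stringsAsFactors = FALSE)
    }))
  })
  rownames(tab) <- NULL
  attr(tab, "source") <- "external_classifier"
  tab
}

#' Classify a dataset of ORFs into user-defined classes
#'
#' Trains an RBF-SVC on the labelled training ORFs (or reuses a pre-trained
#' model) and assigns every query ORF the class with the highest coupled
#' probability. Training ids are echoed with their given labels and flagged
#' `training = TRUE`; their model probabilities are still reported. When
#' `outDir` is given, writes `predictions.tsv` and one FASTA per class; the
#' per-class FASTAs partition the input.
#'
#' @param orfs query ORFs: an [OrfSet-class], named `DNAStringSet`, or FASTA
#'   path.
#' @param classTable from [loadClassTable()] /
#'   [externalClassifierLabels()]; may be `NULL` when `model` is given.
#' @param model optional pre-trained [CodonClassifier-class]; when supplied,
#'   no training happens and all ORFs are scored as queries.
#' @param config from [classifierConfig()].
#' @param codeId genetic-code table id of the run (checked against a
#'   supplied model's metadata).
#' @param outDir optional output directory.
#' @return list with `predictions` (data.frame: `orf_id`, `label`,
#'   `training`, one probability column per class) and `model`.
#' @export
classifyDataset <- function(orfs, classTable = NULL, model = NULL,
                            config = classifierConfig(), codeId = "1",
                            outDir = NULL) {
  if (is.character(orfs) && length(orfs) == 1L)
    orfs <- readTranscripts(orfs)
  seqs <- if (is(orfs, "OrfSet")) ntSeqs(orfs) else orfs
  if (is.null(classTable) && is.null(model))
    stop("either a class table or a pre-trained model is required")
  X <- tokenizeCodons(seqs)
  if (is.null(model)) {
    classTable <- if (is.character(classTable))
      loadClassTable(classTable, names(seqs)) else classTable
    trainIdx <- match(classTable$orf_id, names(seqs))
    model <- trainClassifier(X[trainIdx, , drop = FALSE],
                             classTable$label, config, codeId = codeId)
  } else {
    checkModelCode(model, codeId)
  }
  probs <- predictProbabilities(model, X)
  labels <- modelClasses(model)[max.col(probs, ties.method = "first")]
  training <- rep(FALSE, length(seqs))
  if (!is.null(classTable)) {
    trainIdx <- match(classTable$orf_id, names(seqs))
    labels[trainIdx] <- classTable$label
    training[trainIdx] <- TRUE
  }
  pred <- data.frame(orf_id = names(seqs), label = labels,
                     training = training, stringsAsFactors = FALSE)
  pred <- cbind(pred, as.data.frame(probs))
  rownames(pred) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.table(pred, file.path(outDir, "predictions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (cl in unique(pred$label))
      writeFasta(seqs[pred$label == cl],
                 file.path(outDir, paste0(sanitizeLabel(cl), ".fasta")))
  }
  list(predictions = pred, model = model)
}

sanitizeLabel <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
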