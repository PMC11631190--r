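#' End-to-end ORF prediction from a transcriptome assembly
#'
#' Runs the full prediction workflow: length filter (optional rRNA screen
#' and isoform clustering), six-frame ORF enumeration under the chosen
#' genetic code, translated search of the transcripts against the reference
#' proteome, training-set construction (in-frame positives from the hits,
#' seeded out-of-frame negatives), RBF-SVC training on codon counts, scoring
#' of every candidate ORF, and per-transcript selection of the candidate
#' with the highest in-frame probability. Deterministic given the seed:
#' reruns write byte-identical outputs.
#'
#' @param transcripts transcript FASTA path or named `DNAStringSet`.
#' @param proteinDb reference proteome FASTA path or named `AAStringSet`.
#' @param outDir optional output directory; when given, writes
#'   `orfs_nt.fasta`, `orfs_aa.fasta`, `candidates.tsv`,
#'   `model.orfsieve.json` and `manifest.json`.
#' @param codeId NCBI genetic-code table id (default 1; use 6 for ciliate).
#' @param minTranscript minimum transcript length, nt (default 300).
#' @param minOrf minimum ORF length, nt (default 150).
#' @param partial include partial ORFs as candidates (default `FALSE`).
#' @param cluster collapse redundant isoforms before prediction
#'   (default `TRUE`).
#' @param rrnaRef optional rRNA reference FASTA/`DNAStringSet` enabling the
#'   internal rRNA screen.
#' @param seed integer seed for all stochastic steps.
#' @param search translated-search settings from [searchParams()].
#' @param config classifier settings; defaults to
#'   `classifierConfig(seed = seed)`.
#' @return list: `selected` ([OrfSet-class], one ORF per transcript),
#'   `candidates` ([OrfSet-class]), `probabilities` (named in-frame
#'   probability per candidate), `model` ([CodonClassifier-class]),
#'   `training` (the training set), `hits`, `counts` (filtering log).
#' @export
runPredict <- function(transcripts, proteinDb, outDir = NULL, codeId = "1",
                       minTranscript = 300L, minOrf = 150L, partial = FALSE,
                       cluster = TRUE, rrnaRef = NULL, seed = 42L,
                       search = searchParams(),
                       config = classifierConfig(seed = seed)) {
  if (is.character(transcripts)) transcripts <- readTranscripts(transcripts)
  if (is.character(proteinDb)) proteinDb <- readProteins(proteinDb)
  counts <- list(input = length(transcripts))
  tx <- filterByLength(transcripts, minTranscript)
  counts$short_removed <- counts$input - length(tx)
  if (!is.null(rrnaRef)) {
    scr <- screenRrna(tx, rrnaRef)
    counts$rrna_flagged <- length(scr$flagged)
    tx <- scr$kept
  }
  if (isTRUE(cluster)) {
    cl <- clusterIsoforms(tx)
    counts$isoforms_collapsed <- length(tx) - length(cl$representatives)
    tx <- cl$representatives
  }
  counts$analyzed <- length(tx)
  if (length(tx) == 0L) stop("no transcripts left after filtering")

  candidates <- enumerateOrfs(tx, code = geneticCode(codeId),
                              minLen = minOrf, partial = partial)
  counts$candidate_orfs <- length(candidates)
  message("enumerated ", length(candidates), " candidate ORFs from ",
          length(tx), " transcripts")

  hits <- runReferenceSearch(tx, proteinDb, params = search)
  counts$reference_hits <- nrow(hits)
  training <- buildTrainingSet(hits, tx, seed = seed, minLen = minOrf)
  if (length(training$positives) == 0L)
    stop("zero training positives: no reference-proteome hits usable; ",
         "try a different (closer) reference proteome")
  counts$training_pairs <- length(training$positives)

  X <- rbind(tokenizeCodons(training$positives),
             tokenizeCodons(training$negatives))
  model <- trainClassifier(X, training$labels, config, codeId = codeId)
  probs <- predictProbabilities(model, tokenizeCodons(candidates))
  inFrame <- setNames(probs[, "in-frame"], orfInfo(candidates)$orf_id)
  selected <- selectBestOrfs(candidates, inFrame)
  counts$selected <- length(selected)

  result <- list(selected = selected, candidates = candidates,
                 probabilities = inFrame, model = model,
                 training = training, hits = hits, counts = counts)
  if (!is.null(outDir))
    writePredictOutputs(result, outDir, codeId, minTranscript, minOrf,
                        partial, cluster, seed, config)
  result
}

writePredictOutputs <- function(result, outDir, codeId, minTranscript,
                                minOrf, partial, cluster, seed, config) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeFasta(orfFasta(result$selected), file.path(outDir, "orfs_nt.fasta"))
  aa <- aaSeqs(result$selected)
  names(aa) <- names(orfFasta(result$selected))
  writeFasta(aa, file.path(outDir, "orfs_aa.fasta"))
  cand <- orfInfo(result$candidates)
  cand$in_frame_prob <- unname(result$probabilities[cand$orf_id])
  write.table(cand, file.path(outDir, "candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  saveModel(result$model, file.path(outDir, "model.orfsieve.json"))
  manifest <- list(
    mode = "predict",
    package_version = as.character(packageVersion("ORFsieve")),
    parameters = list(code_table_id = as.character(codeId),
                      min_transcript = minTranscript, min_orf = minOrf,
                      partial = partial, cluster = cluster, seed = seed,
                      classifier = config[c("cRange", "folds", "nTrials",
                                            "seed", "normalizeLength")]),
    counts = result$counts,
    training_hash = result$model@trainingHash)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

# FASTA headers carrying the ORF metadata:
# {orf_id} frame={f} start={s} end={e} complete={true|false}
orfFasta <- function(orfs) {
  info <- orfInfo(orfs)
  nt <- ntSeqs(orfs)
  names(nt) <- sprintf("%s frame=%+d start=%d end=%d complete=%s",
                       info$orf_id, info$frame, info$start, info$end,
                       ifelse(info$complete, "true", "false"))
  nt
}

#' End-to-end supervised ORF classification (decontamination)
#'
#' Wraps [classifyDataset()] with run management: reads the query ORFs and
#' label table (or a saved model archive), trains and classifies, and
#' writes `predictions.tsv`, one FASTA per class, the model archive and a
#' run manifest.
#'
#' @param orfs ORF FASTA path or named `DNAStringSet`.
#' @param classTable TSV path or data.frame of training labels (may be
#'   `NULL` when `model` is given).
#' @param model optional [CodonClassifier-class] or saved archive path.
#' @param outDir optional output directory.
#' @param codeId genetic-code table id of the run.
#' @param seed integer seed.
#' @param config classifier settings; defaults to
#'   `classifierConfig(seed = seed)`.
#' @return as [classifyDataset()], plus `counts`.
#' @export
runClassify <- function(orfs, classTable = NULL, model = NULL,
                        outDir = NULL, codeId = "1", seed = 42L,
                        config = classifierConfig(seed = seed)) {
  if (is.character(orfs)) orfs <- readTranscripts(orfs)
  if (is.character(model)) model <- loadModel(model)
  if (is.null(classTable) && is.null(model))
    stop("usage error: provide a class table (-c) or a model archive")
  if (is.character(classTable))
    classTable <- loadClassTable(classTable, names(orfs))
  res <- classifyDataset(orfs, classTable = classTable, model = model,
                         config = config, codeId = codeId, outDir = outDir)
  res$counts <- list(query_orfs = length(orfs),
                     training = sum(res$predictions$training),
                     classes = length(modelClasses(res$model)))
  if (!is.null(outDir)) {
    saveModel(res$model, file.path(outDir, "model.orfsieve.json"))
    manifest <- list(
      mode = "classify",
      package_version = as.character(packageVersion("ORFsieve")),
      parameters = list(code_table_id = as.character(codeId), seed = seed,
                        classifier = config[c("cRange", "folds", "nTrials",
                                              "seed", "normalizeLength")]),
      counts = res$counts)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
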