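#' Tokenize ORFs as in-frame codon counts
#'
#' Counts non-overlapping, in-frame codons of each sequence over the fixed
#' lexicographic 64-codon vocabulary (AAA ... TTT). Codons containing a
#' non-ACGT character are dropped; a trailing partial codon is ignored.
#'
#' @param x an [OrfSet-class], `DNAStringSet`, or character vector of
#'   nucleotide sequences.
#' @return integer matrix (sequences x 64 codons), rownames from sequence
#'   names, colnames the codon vocabulary.
#' @examples
#' tokenizeCodons(c(orf1 = "ATGAAATAG"))[, c("ATG", "AAA", "TAG")]
#' @export
tokenizeCodons <- function(x) {
  if (is(x, "OrfSet")) x <- ntSeqs(x)
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (length(x) == 0L || any(Biostrings::width(x) == 0L))
    stop("cannot tokenize empty sequences")
  counts <- Biostrings::trinucleotideFrequency(x, step = 3L)
  counts <- counts[, CODON_VOCABULARY, drop = FALSE]
  rownames(counts) <- names(x)
  counts
}

#' Configuration for RBF-SVC training
#'
#' The kernel is fixed to the radial basis function. Only the soft-margin
#' cost C is searched: `nTrials` log-uniform draws from `cRange`
#' (default `[1e-8, 10]`), each scored by mean `folds`-fold (default 5)
#' cross-validated accuracy under the given seed. Gamma uses the
#' data-dependent default `1 / (64 * var(X))`.
#'
#' @param cRange two positive numbers, the C search range.
#' @param folds number of CV folds (>= 2).
#' @param nTrials number of C draws (default 25).
#' @param seed integer seed governing draws, folds and calibration.
#' @param normalizeLength divide codon counts by the codon total per ORF,
#'   removing length information from the RBF distances (default `FALSE`:
#'   raw counts).
#' @return validated configuration list.
#' @export
classifierConfig <- function(cRange = c(1e-8, 10), folds = 5L,
                             nTrials = 25L, seed = 1L,
                             normalizeLength = FALSE) {
  stopifnot(length(cRange) == 2L, all(cRange > 0), folds >= 2L,
            nTrials >= 1L)
  list(kernel = "rbf", cRange = sort(as.numeric(cRange)),
       folds = as.integer(folds), nTrials = as.integer(nTrials),
       seed = as.integer(seed), normalizeLength = isTRUE(normalizeLength))
}

#' Train the RBF support vector classifier on codon counts
#'
#' Fits a multiclass SVC with probability output on codon-count features.
#' The cost C is selected by seeded random search over the configured range,
#' maximizing mean cross-validated accuracy (ties resolve to the largest
#' C). The final model is one binary SVM per class pair (one-vs-one, via
#' libsvm through e1071); per-pair probability calibration fits a Platt
#' sigmoid to decision values collected from a seeded internal
#' cross-validation, and multiclass probabilities are obtained by pairwise
#' coupling. All randomness is governed by `config$seed`, so identical
#' inputs and seed reproduce identical models and predictions.
#'
#' @param X codon-count matrix from [tokenizeCodons()] (n x 64).
#' @param y class labels (factor or character), length n; >= 2 classes,
#'   each with >= 2 examples (a warning is issued below 25 per class, the
#'   recommended minimum training size).
#' @param config from [classifierConfig()].
#' @param codeId genetic-code table id recorded in the model metadata.
#' @return a [CodonClassifier-class].
#' @export
trainClassifier <- function(X, y, config = classifierConfig(),
                            codeId = "1") {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !identical(colnames(X), CODON_VOCABULARY))
    stop("feature columns must be the fixed 64-codon vocabulary")
  if (ncol(X) != 64L) stop("expected 64 codon-count features")
  y <- factor(as.character(y))
  if (nrow(X) != length(y)) stop("X rows and labels differ in length")
  classes <- levels(y)
  if (length(classes) < 2L) stop("need >= 2 classes to train")
  counts <- table(y)
  if (any(counts < 2L))
    stop("class(es) with < 2 examples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  if (any(counts < 25L))
    warning("class(es) below the recommended minimum of 25 training ",
            "examples: ", paste(names(counts)[counts < 25L], collapse = ", "))
  trainingHash <- objectHash(list(unname(X), as.character(y),
                                  config[c("cRange", "folds", "nTrials",
                                           "seed", "normalizeLength")]))
  if (config$normalizeLength) X <- normalizeCounts(X)
  gamma <- gammaScale(X)

  withSeed(config$seed, {
    cGrid <- 10^runif(config$nTrials, log10(config$cRange[1]),
                      log10(config$cRange[2]))
    folds <- stratifiedFolds(y, config$folds)
    cvAcc <- vapply(cGrid, function(C) {
      acc <- vapply(seq_len(config$folds), function(f) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2L) return(NA_real_)
        # coarse SMO tolerance for the search only; the final per-pair
        # fits below use libsvm's default tolerance
        fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], scale = FALSE,
                          kernel = "radial", gamma = gamma, cost = C,
                          tolerance = 0.01)
        mean(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
      }, numeric(1))
      mean(acc, na.rm = TRUE)
    }, numeric(1))
    # ties resolve to the largest C: on separable data every cost reaches
    # the same CV accuracy, but near-zero costs give decision values of
    # vanishing scale that cannot be sigmoid-calibrated
    best <- max(cGrid[cvAcc == max(cvAcc)])
    pairs <- fitClassPairs(X, y, classes, gamma, best, config$folds)
    new("CodonClassifier", classes = classes,
        vocabulary = CODON_VOCABULARY, pairs = pairs, gamma = gamma,
        cost = best,
        cvTable = data.frame(C = cGrid, accuracy = cvAcc),
        codeId = as.character(codeId), seed = config$seed,
        trainingHash = trainingHash,
        version = as.character(packageVersion("ORFsieve")))
  })
}

normalizeCounts <- function(X) {
  tot <- rowSums(X)
  tot[tot == 0] <- 1
  X / tot
}

# sklearn-style "scale" gamma: 1 / (n_features * overall variance)
gammaScale <- function(X) {
  v <- var(as.vector(X))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

stratifiedFolds <- function(y, k) {
  f <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    f[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  f
}

# one-vs-one binary fits with seeded CV Platt calibration; must run inside
# an active withSeed() context
fitClassPairs <- function(X, y, classes, gamma, cost, folds) {
  pairs <- list()
  for (i in seq_len(length(classes) - 1L)) {
    for (j in seq(i + 1L, length(classes))) {
      pos <- classes[i]; neg <- classes[j]
      sel <- y %in% c(pos, neg)
      pX <- X[sel, , drop = FALSE]
      pY <- factor(as.character(y[sel]), levels = c(pos, neg))
      fit <- e1071::svm(pX, pY, scale = FALSE, kernel = "radial",
                        gamma = gamma, cost = cost)
      dv <- attr(predict(fit, pX, decision.values = TRUE),
                 "decision.values")
      sgn <- if (strsplit(colnames(dv), "/")[[1]][1] == pos) 1 else -1
      SV <- unname(as.matrix(fit$SV))
      coefs <- sgn * as.numeric(fit$coefs)
      rho <- sgn * as.numeric(fit$rho)
      # unbiased decision values for sigmoid fitting, from seeded CV
      nf <- min(folds, min(table(pY)))
      cvDec <- rep(NA_real_, nrow(pX))
      if (nf >= 2L) {
        pf <- stratifiedFolds(pY, nf)
        for (f in seq_len(nf)) {
          tr <- pf != f
          if (length(unique(pY[tr])) < 2L) next
          ff <- e1071::svm(pX[tr, , drop = FALSE], pY[tr], scale = FALSE,
                           kernel = "radial", gamma = gamma, cost = cost)
          fdv <- attr(predict(ff, pX[!tr, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
          fsgn <- if (strsplit(colnames(fdv), "/")[[1]][1] == pos) 1 else -1
          cvDec[!tr] <- fsgn * as.numeric(fdv)
        }
      }
      miss <- is.na(cvDec)
      if (any(miss))
        cvDec[miss] <- rbfDecision(pX[miss, , drop = FALSE], SV, coefs, rho,
                                   gamma)
      sig <- plattFit(cvDec, pY == pos)
      pairs[[length(pairs) + 1L]] <-
        list(pos = pos, neg = neg, SV = SV, coefs = coefs, rho = rho,
             probA = sig[1], probB = sig[2])
    }
  }
  pairs
}

# RBF decision values from stored support vectors: > 0 predicts `pos`
rbfDecision <- function(X, SV, coefs, rho, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(SV^2), "+") - 2 * X %*% t(SV)
  d2[d2 < 0] <- 0
  as.numeric(exp(-gamma * d2) %*% coefs) - rho
}

# Platt sigmoid fit P(pos|dec) = 1/(1+exp(A*dec+B)) by the regularized
# Newton method of Lin, Weng & Keerthi (the libsvm procedure)
plattFit <- function(dec, isPos) {
  prior1 <- sum(isPos); prior0 <- sum(!isPos)
  hiTarget <- (prior1 + 1) / (prior1 + 2)
  loTarget <- 1 / (prior0 + 2)
  t <- ifelse(isPos, hiTarget, loTarget)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fObj <- function(A, B) {
    fApB <- dec * A + B
    sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fval <- fObj(A, B)
  sigma <- 1e-12
  for (it in 1:100) {
    fApB <- dec * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- ifelse(fApB >= 0, 1 / (1 + exp(-fApB)),
                exp(fApB) / (1 + exp(fApB)))
    d2 <- p * q
    h11 <- sum(dec * dec * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(dec * d2)
    d1 <- t - p
    g1 <- sum(dec * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    stepsize <- 1
    while (stepsize >= 1e-10) {
      newA <- A + stepsize * dA; newB <- B + stepsize * dB
      newf <- fObj(newA, newB)
      if (newf < fval + 1e-4 * stepsize * gd) {
        A <- newA; B <- newB; fval <- newf; break
      }
      stepsize <- stepsize / 2
    }
    if (stepsize < 1e-10) break
  }
  c(A = A, B = B)
}

#' Predict per-class probabilities for codon-count vectors
#'
#' Computes RBF decision values from the model's stored support vectors for
#' every class pair, maps each through its Platt sigmoid, and couples the
#' pairwise probabilities into a multiclass simplex (Wu-Lin second
#' approach). Rows sum to 1; the predicted class is the row argmax.
#'
#' @param model a [CodonClassifier-class].
#' @param X codon-count matrix from [tokenizeCodons()].
#' @return numeric matrix (rows = inputs, columns = model classes).
#' @export
predictProbabilities <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model@vocabulary))
    stop("feature columns do not match the model vocabulary (",
         length(model@vocabulary), " codons expected)")
  if (!is.null(colnames(X)) && !identical(colnames(X), model@vocabulary))
    stop("feature column order does not match the model vocabulary")
  classes <- model@classes
  k <- length(classes)
  n <- nrow(X)
  # pairwise P(pos beats neg), clipped as in libsvm
  R <- array(0, dim = c(n, k, k))
  eps <- 1e-7
  for (p in model@pairs) {
    dec <- rbfDecision(X, p$SV, p$coefs, p$rho, model@gamma)
    r <- 1 / (1 + exp(p$probA * dec + p$probB))
    r <- pmin(pmax(r, eps), 1 - eps)
    i <- match(p$pos, classes); j <- match(p$neg, classes)
    R[, i, j] <- r
    R[, j, i] <- 1 - r
  }
  out <- matrix(0, n, k, dimnames = list(rownames(X), classes))
  if (k == 2L) {
    out[, 1] <- R[, 1, 2]
    out[, 2] <- 1 - R[, 1, 2]
  } else {
    for (row in seq_len(n))
      out[row, ] <- coupleProbabilities(R[row, , ])
  }
  out
}

# Wu & Lin (2004) second approach, as implemented in libsvm
coupleProbabilities <- function(r) {
  k <- nrow(r)
  Q <- matrix(0, k, k)
  for (t in seq_len(k)) {
    Q[t, t] <- sum(r[-t, t]^2)
    for (j in seq_len(k)) if (j != t) Q[t, j] <- -r[j, t] * r[t, j]
  }
  p <- rep(1 / k, k)
  eps <- 0.005 / k
  for (iter in 1:100) {
    Qp <- as.numeric(Q %*% p)
    pQp <- sum(p * Qp)
    if (max(abs(Qp - pQp)) < eps) break
    for (t in seq_len(k)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[, t]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  p / sum(p)
}

#' Select the best ORF per transcript by in-frame probability
#'
#' Per transcript, keeps the candidate with the highest in-frame
#' probability; exact probability ties resolve to the longer ORF, remaining
#' ties to the smaller start coordinate, then to the positive-strand frame.
#' Transcripts without candidates are omitted and counted.
#'
#' @param orfs an [OrfSet-class] of candidates.
#' @param probs named numeric vector of in-frame probabilities (names =
#'   `orf_id`), e.g. the `"in-frame"` column of [predictProbabilities()].
#' @return an [OrfSet-class] with one ORF per transcript; attribute
#'   `"n_omitted"` counts transcripts without candidates (always 0 here,
#'   reported for pipeline logs).
#' @export
selectBestOrfs <- function(orfs, probs) {
  info <- orfInfo(orfs)
  if (!all(info$orf_id %in% names(probs)))
    stop("every candidate ORF needs an in-frame probability")
  p <- unname(probs[info$orf_id])
  len <- info$end - info$start + 1L
  ord <- order(info$transcript_id, -p, -len, info$start, info$frame < 0L)
  first <- !duplicated(info$transcript_id[ord])
  sel <- sort(ord[first])
  out <- subsetOrfSet(orfs, sel)
  attr(out, "n_omitted") <- 0L
  out
}

#' Save / load a trained classifier
#'
#' The archive is a single JSON document holding the model metadata
#' (classes, codon vocabulary, genetic-code table, seed, training hash,
#' package and format versions) and all numeric arrays (support vectors,
#' dual coefficients, intercepts, sigmoid parameters) printed at 17
#' significant digits, so doubles round-trip exactly and a reloaded model
#' reproduces bit-identical predictions. No code is stored or executed on
#' load.
#'
#' @param model a [CodonClassifier-class].
#' @param path archive path (conventionally `.orfsieve.json`).
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the
#'   reconstructed [CodonClassifier-class].
#' @export
saveModel <- function(model, path) {
  doc <- list(
    format_version = MODEL_FORMAT_VERSION,
    package_version = model@version,
    classes = model@classes,
    vocabulary = model@vocabulary,
    code_table_id = model@codeId,
    seed = model@seed,
    training_hash = model@trainingHash,
    gamma = num2chr(model@gamma),
    cost = num2chr(model@cost),
    cv_C = num2chr(model@cvTable$C),
    cv_accuracy = num2chr(model@cvTable$accuracy),
    pairs = lapply(model@pairs, function(p) list(
      pos = p$pos, neg = p$neg,
      n_sv = nrow(p$SV),
      sv = num2chr(as.numeric(t(p$SV))),   # row-major
      coefs = num2chr(p$coefs),
      rho = num2chr(p$rho),
      probA = num2chr(p$probA), probB = num2chr(p$probB))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot read model archive '", path,
                         "': corrupted or not a model file (",
                         conditionMessage(e), ")"))
  need <- c("format_version", "classes", "vocabulary", "pairs", "gamma",
            "cost", "code_table_id", "seed")
  if (!all(need %in% names(doc)))
    stop("model archive '", path, "' is missing required fields: ",
         paste(setdiff(need, names(doc)), collapse = ", "))
  if (!identical(as.character(doc$format_version), MODEL_FORMAT_VERSION))
    stop("model archive format version '", doc$format_version,
         "' is not supported by this package version")
  if (length(doc$vocabulary) != 64L)
    stop("model archive vocabulary has ", length(doc$vocabulary),
         " entries; 64 codons expected")
  pairs <- doc$pairs
  if (is.data.frame(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.list(pairs[i, ]))
  pairs <- lapply(pairs, function(p) {
    nSV <- as.integer(p$n_sv)
    sv <- matrix(chr2num(unlist(p$sv)), nrow = nSV, ncol = 64L,
                 byrow = TRUE)
    list(pos = as.character(p$pos), neg = as.character(p$neg), SV = sv,
         coefs = chr2num(unlist(p$coefs)), rho = chr2num(p$rho),
         probA = chr2num(p$probA), probB = chr2num(p$probB))
  })
  new("CodonClassifier",
      classes = as.character(doc$classes),
      vocabulary = as.character(doc$vocabulary),
      pairs = pairs,
      gamma = chr2num(doc$gamma), cost = chr2num(doc$cost),
      cvTable = data.frame(C = chr2num(doc$cv_C),
                           accuracy = chr2num(doc$cv_accuracy)),
      codeId = as.character(doc$code_table_id),
      seed = as.integer(doc$seed),
      trainingHash = as.character(doc$training_hash),
      version = as.character(doc$package_version))
}

# warn when a model trained under one genetic code is applied in a run
# using another
checkModelCode <- function(model, codeId) {
  if (!identical(model@codeId, as.character(codeId)))
    warning("model was trained under genetic code ", model@codeId,
            " but is being applied under code ", codeId)
  invisible(model)
}
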