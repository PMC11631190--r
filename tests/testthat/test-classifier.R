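test_that("codon tokenization matches hand counts and the stride-3 oracle", {
  x <- tokenizeCodons(c(a = "ATGAAATAG"))
  expect_identical(unname(x[1, c("ATG", "AAA", "TAG")]), rep(1L, 3))
  expect_identical(sum(x), 3L)

  x <- tokenizeCodons(c(b = "ATGNNAAAA"))  # NNA dropped, trailing A ignored
  expect_identical(unname(x[1, c("ATG", "AAA")]), c(1L, 1L))
  expect_identical(sum(x), 2L)

  expect_error(tokenizeCodons(character(0)), "empty")
  expect_error(tokenizeCodons(c(a = "")), "empty")

  seqs <- withr::with_seed(151, vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 3 * sample(30:80, 1),
                 replace = TRUE, prob = c(rep(0.245, 4), 0.02)),
          collapse = ""), character(1)))
  names(seqs) <- paste0("s", 1:100)
  got <- tokenizeCodons(seqs)
  oracle <- codonCountOracle(seqs)
  expect_identical(unname(got), unname(oracle))
})

test_that("distinct-fingerprint taxa are classified near perfectly", {
  taxa <- distinctTaxa()
  pool <- simulateClassifiedOrfs(taxa, 300, seed = 161)
  X <- tokenizeCodons(pool$orfs)
  y <- pool$labels$label
  tr <- withr::with_seed(162, unlist(lapply(split(seq_along(y), y),
                                            sample, 200)))
  m <- trainClassifier(X[tr, ], y[tr], classifierConfig(seed = 163))
  acc <- mean(predLabels(predictProbabilities(m, X[-tr, ])) == y[-tr])
  oracleAcc <- centroidAccuracy(X[tr, ], y[tr], X[-tr, ], y[-tr])
  expect_gte(oracleAcc, 0.99)  # the fixture is separable by composition
  expect_gte(acc, 0.99)        # the SVC matches the simple oracle
})

test_that("training is deterministic and matches e1071 decision values", {
  taxa <- distinctTaxa()
  pool <- simulateClassifiedOrfs(taxa, 40, seed = 171)
  X <- tokenizeCodons(pool$orfs)
  y <- pool$labels$label
  cfg <- classifierConfig(seed = 172, nTrials = 8)
  m1 <- trainClassifier(X, y, cfg)
  m2 <- trainClassifier(X, y, cfg)
  expect_identical(m1@cost, m2@cost)
  expect_identical(m1@pairs[[1]]$coefs, m2@pairs[[1]]$coefs)
  expect_identical(predictProbabilities(m1, X), predictProbabilities(m2, X))

  # independent cross-check: refit the selected pair SVM directly with
  # e1071 and compare its decision values with the stored-array computation
  fit <- e1071::svm(X, factor(y, levels = modelClasses(m1)), scale = FALSE,
                    kernel = "radial", gamma = m1@gamma, cost = m1@cost)
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  sgn <- if (strsplit(colnames(dv), "/")[[1]][1] == modelClasses(m1)[1])
    1 else -1
  mine <- ORFsieve:::rbfDecision(X, m1@pairs[[1]]$SV, m1@pairs[[1]]$coefs,
                                 m1@pairs[[1]]$rho, m1@gamma)
  expect_lt(max(abs(mine - sgn * as.numeric(dv))), 1e-8)
})

test_that("probability rows form a simplex and are deterministic", {
  taxa <- list(makeTaxonModel("a", 25, 1, seed = 181),
               makeTaxonModel("b", 55, 1, seed = 182),
               makeTaxonModel("c", 85, 1, seed = 183))
  pool <- simulateClassifiedOrfs(taxa, 40, seed = 184)
  X <- tokenizeCodons(pool$orfs)
  m <- trainClassifier(X, pool$labels$label,
                       classifierConfig(seed = 185, nTrials = 8))
  Xq <- withr::with_seed(186,
    matrix(rpois(500 * 64, 3), 500, 64,
           dimnames = list(NULL, modelVocabulary(m))))
  p <- predictProbabilities(m, Xq)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-9)
  expect_true(all(p >= 0 & p <= 1))
  # identical input rows give identical output rows
  pdup <- predictProbabilities(m, Xq[c(1, 1, 2), ])
  expect_identical(pdup[1, ], pdup[2, ])
  # a training example of a well-separated fixture scores > 0.9 for its class
  ptr <- predictProbabilities(m, X)
  expect_gt(ptr[1, pool$labels$label[1]], 0.9)
  # vocabulary mismatch is an error
  expect_error(predictProbabilities(m, Xq[, 1:63]), "vocabulary")
})

test_that("shuffled labels on separable data give chance-level CV accuracy", {
  taxa <- distinctTaxa()
  pool <- simulateClassifiedOrfs(taxa, 60, seed = 191)
  X <- tokenizeCodons(pool$orfs)
  yShuf <- withr::with_seed(192, sample(pool$labels$label))
  m <- suppressWarnings(trainClassifier(X, yShuf,
                                        classifierConfig(seed = 193,
                                                         nTrials = 10)))
  n <- nrow(X)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(m@cvTable$accuracy) - 0.5), 3 * se + 0.05)
})

test_that("degenerate training inputs are rejected or warned about", {
  X <- matrix(1L, 10, 64, dimnames = list(NULL, ORFsieve:::CODON_VOCABULARY))
  expect_error(trainClassifier(X, rep("a", 10)), "2 classes")
  expect_error(trainClassifier(X, c(rep("a", 9), "b")), "< 2 examples")
  Xr <- withr::with_seed(195, matrix(rpois(40 * 64, 2), 40, 64,
                                     dimnames = list(NULL,
                                                     ORFsieve:::CODON_VOCABULARY)))
  expect_warning(trainClassifier(Xr, rep(c("a", "b"), 20),
                                 classifierConfig(nTrials = 2)),
                 "minimum of 25")
})

test_that("duplicating every training point leaves held-out labels unchanged", {
  taxa <- distinctTaxa()
  pool <- simulateClassifiedOrfs(taxa, 60, seed = 201)
  X <- tokenizeCodons(pool$orfs)
  y <- pool$labels$label
  tr <- c(1:30, 61:90)
  cfg <- classifierConfig(seed = 202, nTrials = 8)
  m1 <- trainClassifier(X[tr, ], y[tr], cfg)
  m2 <- trainClassifier(X[c(tr, tr), ], y[c(tr, tr)], cfg)
  expect_identical(predLabels(predictProbabilities(m1, X[-tr, ])),
                   predLabels(predictProbabilities(m2, X[-tr, ])))
})

test_that("best-ORF selection maximizes in-frame probability with documented tie-breaks", {
  info <- data.frame(
    orf_id = c("o1", "o2", "o3", "o4", "o5", "o6"),
    transcript_id = c("t1", "t1", "t2", "t2", "t3", "t3"),
    frame = c(1L, 2L, 1L, 2L, -1L, 1L),
    start = c(1L, 2L, 1L, 31L, 4L, 4L),
    end = c(300L, 151L, 300L, 180L, 153L, 153L),
    complete = TRUE)
  nt <- Biostrings::DNAStringSet(vapply(
    info$end - info$start + 1L, strrep, "", x = "A"))
  names(nt) <- info$orf_id
  aa <- Biostrings::AAStringSet(vapply(
    (info$end - info$start + 1L) / 3L, strrep, "", x = "K"))
  names(aa) <- info$orf_id
  orfs <- ORFsieve:::OrfSet(info, nt, aa, "1")
  # t1: plain argmax; t2: tie -> longer; t3: tie + equal length -> the
  # positive frame (equal start)
  probs <- c(o1 = 0.97, o2 = 0.61, o3 = 0.90, o4 = 0.90, o5 = 0.80,
             o6 = 0.80)
  sel <- orfInfo(selectBestOrfs(orfs, probs))
  expect_identical(sel$orf_id, c("o1", "o3", "o6"))
  expect_error(selectBestOrfs(orfs, probs[-1]), "probability")
})

test_that("model archives round-trip bit-identically and reject corruption", {
  taxa <- distinctTaxa()
  pool <- simulateClassifiedOrfs(taxa, 40, seed = 211)
  X <- tokenizeCodons(pool$orfs)
  m <- trainClassifier(X, pool$labels$label,
                       classifierConfig(seed = 212, nTrials = 6),
                       codeId = "6")
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(predictProbabilities(m2, X), predictProbabilities(m, X))
  expect_identical(modelClasses(m2), modelClasses(m))
  expect_identical(modelCode(m2), "6")
  expect_identical(modelSeed(m2), 212L)

  # truncated vocabulary is rejected
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$vocabulary <- doc$vocabulary[1:63]
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad, auto_unbox = TRUE)
  expect_error(loadModel(bad), "64")

  # corrupted archive is an explicit error, never a silent fallback
  writeLines("not json at all {", bad)
  expect_error(loadModel(bad), "corrupted|cannot read")

  # genetic-code mismatch between model and run is surfaced
  expect_warning(ORFsieve:::checkModelCode(m, "1"), "code")
})
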