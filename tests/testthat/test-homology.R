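# fixture: transcripts that embed translations of known proteins in
# planted frames, plus unrelated random transcripts
plantedSearchFixture <- function(nProt = 30, seed = 111) {
  withr::with_seed(seed, {
    tax <- makeTaxonModel("ref", gc3Target = 50, divergence = 1, seed = seed)
    code <- geneticCode(1)
    prots <- character(nProt); txs <- character(nProt); frames <- integer(nProt)
    for (i in seq_len(nProt)) {
      cds <- ORFsieve:::sampleCds(tax, 120, code)
      prots[i] <- sub("\\*$", "", translateSeq(cds))
      utr5 <- paste(sample(c("A", "C", "G", "T"), sample(20:80, 1),
                           replace = TRUE), collapse = "")
      utr3 <- paste(sample(c("A", "C", "G", "T"), sample(20:80, 1),
                           replace = TRUE), collapse = "")
      tx <- paste0(utr5, cds, utr3)
      fr <- ((nchar(utr5)) %% 3L) + 1L
      if (runif(1) < 0.5) {
        # after reverse-complementing, reading restarts on the original
        # strand at the CDS start, so the frame offset is set by the 5' UTR
        tx <- ORFsieve:::revcompChr(tx)
        fr <- -((nchar(utr5) %% 3L) + 1L)
      }
      txs[i] <- tx; frames[i] <- fr
    }
    transcripts <- Biostrings::DNAStringSet(txs)
    names(transcripts) <- sprintf("q%03d", seq_len(nProt))
    db <- Biostrings::AAStringSet(prots)
    names(db) <- sprintf("p%03d", seq_len(nProt))
    list(transcripts = transcripts, db = db, frames = frames)
  })
}

test_that("exact in-frame copies are found with full subject coverage", {
  tax <- makeTaxonModel("t", 50, 1, seed = 5)
  cds <- withr::with_seed(5, ORFsieve:::sampleCds(tax, 100, geneticCode(1)))
  prot <- sub("\\*$", "", translateSeq(cds))
  hits <- runReferenceSearch(
    Biostrings::DNAStringSet(c(q = cds)),
    Biostrings::AAStringSet(c(p = prot)))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$qframe, 1L)
  expect_equal(hits$pident, 100)
  expect_equal(hits$scov, 1.0)
  expect_lte(hits$evalue, 1e-30)
})

test_that("random transcripts sharing no seed word yield no hit", {
  db <- Biostrings::AAStringSet(c(p = strrep("MKLVDE", 40)))
  tx <- Biostrings::DNAStringSet(c(q = strrep("ACGT", 200)))
  hits <- runReferenceSearch(tx, db)
  expect_identical(nrow(hits), 0L)
  expect_error(runReferenceSearch(tx, Biostrings::AAStringSet()), "empty")
})

test_that("reported frames match the planted frames", {
  fx <- plantedSearchFixture(30, seed = 131)
  hits <- runReferenceSearch(fx$transcripts, fx$db)
  expect_gte(nrow(hits), 29)
  m <- match(hits$qid, names(fx$transcripts))
  expect_gte(mean(hits$qframe == fx$frames[m]), 0.99)
  # best-hit-only: at most one hit per query
  expect_false(anyDuplicated(hits$qid) > 0)
})

test_that("training sets pair each positive with one seeded out-of-frame negative", {
  fx <- plantedSearchFixture(25, seed = 141)
  hits <- runReferenceSearch(fx$transcripts, fx$db)
  ts1 <- buildTrainingSet(hits, fx$transcripts, seed = 7)
  ts2 <- buildTrainingSet(hits, fx$transcripts, seed = 7)
  expect_identical(length(ts1$positives), length(ts1$negatives))
  expect_identical(as.character(ts1$negatives), as.character(ts2$negatives))
  ts3 <- buildTrainingSet(hits, fx$transcripts, seed = 8)
  expect_false(identical(as.character(ts1$negatives),
                         as.character(ts3$negatives)))

  # positives translate without internal stops
  aa <- translateSeq(as.character(ts1$positives))
  expect_false(any(grepl("\\*", sub("\\*$", "", aa))))

  # negatives: internal stop, or codon usage closer to background than to
  # the coding pool (codon-frequency distance oracle)
  negAa <- translateSeq(as.character(ts1$negatives))
  hasStop <- grepl("\\*", sub("\\*$", "", negAa))
  posFreq <- colSums(tokenizeCodons(ts1$positives))
  posFreq <- posFreq / sum(posFreq)
  bg <- rep(1 / 64, 64)
  negCounts <- tokenizeCodons(ts1$negatives)
  closerToBg <- vapply(seq_len(nrow(negCounts)), function(i) {
    f <- negCounts[i, ] / max(sum(negCounts[i, ]), 1)
    sum(abs(f - bg)) <= sum(abs(f - posFreq))
  }, logical(1))
  expect_true(all(hasStop | closerToBg))
})

test_that("missing external search backend raises an explicit error", {
  withr::with_envvar(c(PATH = tempdir()), {
    tx <- Biostrings::DNAStringSet(c(q = strrep("ACGT", 100)))
    db <- Biostrings::AAStringSet(c(p = strrep("MKLV", 30)))
    expect_error(runReferenceSearch(tx, db, backend = "diamond"), "diamond")
  })
})
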