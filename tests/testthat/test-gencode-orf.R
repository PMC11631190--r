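test_that("genetic-code tables cover the required ids and table 6 reassigns stops", {
  for (id in c(1, 4, 6, 10, 12, 29, 30)) {
    code <- geneticCode(id)
    expect_length(code, 64L)
    expect_false(anyNA(code))
  }
  c6 <- geneticCode(6)
  expect_identical(unname(c6[c("TAA", "TAG", "TGA")]), c("Q", "Q", "*"))
  expect_identical(unname(geneticCode(29)[c("TAA", "TAG")]), c("Y", "Y"))
  expect_identical(unname(geneticCode(30)[c("TAA", "TAG")]), c("E", "E"))
  expect_error(geneticCode(99), "unknown")
})

test_that("translation matches hand examples and a codon-lookup oracle", {
  expect_identical(translateSeq("ATGAAATGA"), "MK*")
  expect_identical(translateSeq("ATGTAATGA", code = 6), "MQ*")
  expect_identical(translateSeq("ATGNNAAAA"), "MXK")
  expect_error(translateSeq("ATGA"), "divisible")

  nt <- as.character(randomTranscripts(5, 999, seed = 61))
  lut <- Biostrings::getGeneticCode("1")
  oracle <- vapply(nt, function(s) {
    cod <- substring(s, seq(1, 997, 3), seq(3, 999, 3))
    aa <- unname(lut[cod]); aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  expect_identical(translateSeq(nt), oracle)
})

test_that("complete ORF enumeration matches hand cases and strand symmetry", {
  tx <- Biostrings::DNAStringSet(c(t1 = "CCATGAAATAGGC"))
  o <- orfInfo(enumerateOrfs(tx, minLen = 9))
  expect_identical(o[, c("frame", "start", "end", "complete")],
                   data.frame(frame = 3L, start = 3L, end = 11L,
                              complete = TRUE))
  expect_identical(as.character(aaSeqs(enumerateOrfs(tx, minLen = 9))),
                   c(t1.orf1 = "MK"))

  rc <- Biostrings::DNAStringSet(
    c(t1 = as.character(Biostrings::reverseComplement(tx[[1]]))))
  o2 <- orfInfo(enumerateOrfs(rc, minLen = 9))
  expect_identical(o2$frame, -3L)
  expect_identical(as.character(aaSeqs(enumerateOrfs(rc, minLen = 9))),
                   c(t1.orf1 = "MK"))
})

test_that("enumeration equals the brute-force six-frame oracle on random transcripts", {
  tx <- randomTranscripts(60, 1000, seed = 71)
  for (codeId in c("1", "6")) {
    got <- canonicalOrfTable(enumerateOrfs(tx, code = geneticCode(codeId),
                                           minLen = 150))
    want <- bruteForceOrfs(tx, Biostrings::getGeneticCode(codeId),
                           minLen = 150)
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("reverse-complementing transcripts negates frames and reflects coordinates", {
  tx <- randomTranscripts(20, 900, seed = 81)
  rc <- Biostrings::reverseComplement(tx)
  names(rc) <- names(tx)
  a <- canonicalOrfTable(enumerateOrfs(tx, minLen = 150))
  b <- orfInfo(enumerateOrfs(rc, minLen = 150))
  L <- Biostrings::width(tx)[match(b$transcript_id, names(tx))]
  reflected <- data.frame(transcript_id = b$transcript_id,
                          frame = -b$frame,
                          start = L - b$end + 1L, end = L - b$start + 1L,
                          complete = b$complete, stringsAsFactors = FALSE)
  reflected <- reflected[order(reflected$transcript_id, reflected$frame,
                               reflected$start), ]
  rownames(reflected) <- NULL
  expect_identical(a, reflected)
})

test_that("no translated ORF contains an internal stop", {
  tx <- randomTranscripts(30, 1200, seed = 91)
  for (codeId in c("1", "6")) {
    aa <- as.character(aaSeqs(enumeratePartialOrfs(
      tx, code = geneticCode(codeId), minLen = 150)))
    expect_false(any(grepl("\\*", aa)))
  }
})

test_that("partial enumeration adds startless and edge-truncated stretches only", {
  p <- orfInfo(enumeratePartialOrfs(
    Biostrings::DNAStringSet(c(t2 = "AAAAAATAG")), minLen = 6))
  f1 <- p[p$frame == 1L, ]
  expect_identical(f1[, c("start", "end", "complete")],
                   data.frame(start = 1L, end = 9L, complete = FALSE))

  # a transcript that is exactly one complete ORF: nothing extra in frame +1
  cds <- "ATGAAACCCGGGTTTACGTGA"
  p2 <- orfInfo(enumeratePartialOrfs(
    Biostrings::DNAStringSet(c(t3 = cds)), minLen = 6))
  f1 <- p2[p2$frame == 1L, ]
  expect_identical(nrow(f1), 1L)
  expect_true(f1$complete)
  expect_identical(c(f1$start, f1$end), c(1L, 21L))

  # oracle equivalence including partials
  tx <- randomTranscripts(40, 700, seed = 101)
  got <- canonicalOrfTable(enumeratePartialOrfs(tx, minLen = 150))
  want <- bruteForceOrfs(tx, minLen = 150, partial = TRUE)
  rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("table-6 enumeration reads through TAA/TAG", {
  # CDS with internal TAA and TAG, terminated by TGA
  cds <- paste0("ATG", "TAA", "AAA", "TAG", "CCC", "TGA")
  tx <- Biostrings::DNAStringSet(c(t = paste0("GG", cds, "GG")))
  o6 <- orfInfo(enumerateOrfs(tx, code = geneticCode(6), minLen = 9))
  o6 <- o6[o6$frame == 3L, ]
  expect_identical(c(o6$start, o6$end), c(3L, 20L))
  expect_identical(unname(as.character(aaSeqs(enumerateOrfs(
    tx, code = geneticCode(6), minLen = 9))[o6$orf_id])), "MQKQP")
  # under the standard code the same region stops at the internal TAA
  o1 <- orfInfo(enumerateOrfs(tx, code = geneticCode(1), minLen = 3))
  o1 <- o1[o1$frame == 3L, ]
  expect_identical(c(o1$start, o1$end), c(3L, 8L))
})
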