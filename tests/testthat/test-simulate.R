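test_that("taxon models hit exact GC3 class totals and respond to divergence", {
  a <- makeTaxonModel("a", gc3Target = 20, divergence = 1, seed = 301)
  b <- makeTaxonModel("b", gc3Target = 80, divergence = 1, seed = 302)
  # direct frequency computation: expected GC3 of the usage equals target
  gc3Of <- function(m) {
    u <- m@codonUsage
    100 * sum(u[substr(names(u), 3, 3) %in% c("C", "G")])
  }
  expect_equal(gc3Of(a), 20, tolerance = 1e-10)
  expect_equal(gc3Of(b), 80, tolerance = 1e-10)
  expect_gte(sum(abs(a@codonUsage - b@codonUsage)), 0.5)

  # divergence 0 with the shared base seed gives identical usage vectors
  c1 <- makeTaxonModel("c1", 50, divergence = 0, seed = 311)
  c2 <- makeTaxonModel("c2", 50, divergence = 0, seed = 312)
  expect_identical(c1@codonUsage, c2@codonUsage)

  # 10,000 sampled codons land within the binomial bound of the target
  m <- makeTaxonModel("m", 50, divergence = 1, seed = 321)
  cods <- withr::with_seed(322,
    sample(names(m@codonUsage), 10000, replace = TRUE,
           prob = m@codonUsage))
  gc3 <- 100 * mean(substr(cods, 3, 3) %in% c("C", "G"))
  expect_gte(gc3, 48); expect_lte(gc3, 52)
})

test_that("transcriptome simulation is reproducible and honors its config", {
  taxa <- list(makeTaxonModel("big", 35, 1, seed = 331),
               makeTaxonModel("small", 75, 1, seed = 332))
  cfg <- simulationConfig(taxa, proportions = c(0.9, 0.1),
                          nTranscripts = 200, antisenseRate = 0,
                          seed = 333)
  sim1 <- simulateTranscriptome(cfg)
  sim2 <- simulateTranscriptome(cfg)
  expect_identical(as.character(sim1$transcripts),
                   as.character(sim2$transcripts))
  expect_identical(sim1$truth, sim2$truth)
  expect_true(all(sim1$truth$frame > 0))          # antisense_rate 0
  expect_identical(length(sim1$proteome), 200L)

  # the truth's CDS coordinates really contain the planted protein
  i <- 1
  cds <- substr(as.character(sim1$transcripts[[i]]),
                sim1$truth$cds_start[i], sim1$truth$cds_end[i])
  expect_identical(sub("\\*$", "", translateSeq(cds)),
                   as.character(sim1$proteome[[i]]))

  # antisense transcripts carry negative frames and reflected coordinates
  cfgA <- simulationConfig(taxa, proportions = c(0.5, 0.5),
                           nTranscripts = 100, antisenseRate = 1,
                           seed = 334)
  simA <- simulateTranscriptome(cfgA)
  expect_true(all(simA$truth$frame < 0))
  j <- 5
  cds <- substr(as.character(simA$transcripts[[j]]),
                simA$truth$cds_start[j], simA$truth$cds_end[j])
  expect_identical(sub("\\*$", "", translateSeq(ORFsieve:::revcompChr(cds))),
                   as.character(simA$proteome[[j]]))
})

test_that("generated CDS codon frequencies track the taxon model", {
  tax <- makeTaxonModel("t", 55, 1, seed = 341)
  pool <- simulateClassifiedOrfs(list(tax, tax), 50,
                                 lenRange = c(300, 400), seed = 342)
  # drop the forced start and terminal stop: they are structural, not
  # drawn from the usage model
  body <- substr(as.character(pool$orfs), 4,
                 nchar(as.character(pool$orfs)) - 3)
  X <- tokenizeCodons(body)
  f <- colSums(X) / sum(X)
  l1 <- sum(abs(f - tax@codonUsage))
  expect_lte(l1, 0.05)
})

test_that("classified ORF pools honor exact counts and are separable when distinct", {
  taxa <- distinctTaxa()
  pool <- simulateClassifiedOrfs(taxa, c(900, 100), seed = 351,
                                 lenRange = c(100, 200))
  expect_identical(as.vector(table(pool$labels$label)[c("taxA", "taxB")]),
                   c(900L, 100L))
  expect_identical(length(pool$orfs), 1000L)

  # distinct fingerprints are linearly separable on (gc12, gc3)
  sub <- c(1:300, 901:1000)
  comp <- computeComposition(pool$orfs[sub])
  lab <- factor(pool$labels$label[sub])
  fit <- suppressWarnings(glm(lab ~ gc12 + gc3, comp, family = binomial))
  acc <- mean((predict(fit) > 0) == (lab == levels(lab)[2]))
  expect_gte(acc, 0.99)
})

test_that("simulations write complete file sets", {
  taxa <- distinctTaxa()
  cfg <- simulationConfig(taxa, nTranscripts = 10, seed = 361)
  dir <- withr::local_tempdir()
  writeSimulation(simulateTranscriptome(cfg), dir)
  expect_setequal(list.files(dir),
                  c("transcripts.fasta", "truth.tsv", "proteome.fasta"))
  tx <- readTranscripts(file.path(dir, "transcripts.fasta"))
  expect_identical(length(tx), 10L)
})
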