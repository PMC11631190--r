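#' Build a taxon codon-usage model for simulation
#'
#' Constructs a codon-usage fingerprint whose expected third-position GC of
#' sampled sense codons equals `gc3Target` exactly: the four third-base
#' classes receive totals `g/2, g/2, (1-g)/2, (1-g)/2` (G, C, A, T with
#' `g = gc3Target/100`), distributed across each class's non-stop codons.
#' Within-class weights interpolate between a shared Dirichlet draw (from
#' `baseSeed`, common to all taxa) and an independent Dirichlet draw (from
#' `seed`): `divergence = 0` gives taxa with identical usage,
#' `divergence = 1` gives independent fingerprints, intermediate values give
#' the "dissimilar" regime between them.
#'
#' @param name taxon label.
#' @param gc3Target target third-position GC, percent in `[0, 100]`.
#' @param divergence distance from the shared base usage, in `[0, 1]`.
#' @param seed integer seed for this taxon's independent draw.
#' @param baseSeed seed of the shared base usage (keep equal across taxa).
#' @param codeId genetic code whose stop codons receive zero usage.
#' @param utrBaseFreqs named A/C/G/T frequencies for untranslated regions.
#' @return a [TaxonModel-class].
#' @export
makeTaxonModel <- function(name, gc3Target, divergence = 1, seed = 1L,
                           baseSeed = 1000L, codeId = "1",
                           utrBaseFreqs = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25)) {
  stopifnot(gc3Target >= 0, gc3Target <= 100,
            divergence >= 0, divergence <= 1)
  code <- geneticCode(codeId)
  sense <- CODON_VOCABULARY[unname(code[CODON_VOCABULARY]) != "*"]
  g <- gc3Target / 100
  classTotal <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  usage <- setNames(numeric(64L), CODON_VOCABULARY)
  third <- substr(sense, 3L, 3L)
  for (b in DNA_BASES) {
    cls <- sense[third == b]
    shared <- withSeed(baseSeed + match(b, DNA_BASES),
                       rdirichlet1(length(cls)))
    indep <- withSeed(seed * 17L + match(b, DNA_BASES),
                      rdirichlet1(length(cls)))
    w <- (1 - divergence) * shared + divergence * indep
    usage[cls] <- classTotal[b] * w / sum(w)
  }
  usage <- usage / sum(usage)
  new("TaxonModel", name = name, codonUsage = usage,
      gc3Target = gc3Target,
      utrBaseFreqs = utrBaseFreqs[DNA_BASES], seed = as.integer(seed))
}

# one flat-Dirichlet draw of length n (uses the active RNG stream)
rdirichlet1 <- function(n) {
  x <- stats::rgamma(n, 1)
  x / sum(x)
}

# sample a CDS: forced ATG start, nCodons - 1 sense codons from the usage,
# one terminal stop of the active code (uses the active RNG stream)
sampleCds <- function(model, nCodons, code) {
  stopifnot(nCodons >= 2L)
  stops <- CODON_VOCABULARY[unname(code[CODON_VOCABULARY]) == "*"]
  body <- sample(CODON_VOCABULARY, nCodons - 1L, replace = TRUE,
                 prob = model@codonUsage)
  stop <- if (length(stops) > 1L) sample(stops, 1L) else stops
  paste0("ATG", paste(body, collapse = ""), stop)
}

sampleUtr <- function(model, len) {
  if (len <= 0L) return("")
  paste(sample(DNA_BASES, len, replace = TRUE,
               prob = model@utrBaseFreqs), collapse = "")
}

#' Simulation configuration for multi-taxon transcript mixtures
#'
#' @param taxa list of [TaxonModel-class] objects.
#' @param proportions mixing proportions over taxa (summing to 1).
#' @param nTranscripts number of transcripts to simulate.
#' @param cdsLenRange CDS length range in sense codons (start included,
#'   stop excluded), default 100-400.
#' @param utrLenRange per-UTR length range in nt, default 30-300.
#' @param antisenseRate fraction of transcripts emitted reverse-complemented.
#' @param codeId genetic-code table id for stops and translations.
#' @param seed integer seed.
#' @return validated configuration list.
#' @export
simulationConfig <- function(taxa, proportions = NULL, nTranscripts = 500L,
                             cdsLenRange = c(100L, 400L),
                             utrLenRange = c(30L, 300L),
                             antisenseRate = 0, codeId = "1", seed = 1L) {
  if (is.null(proportions))
    proportions <- rep(1 / length(taxa), length(taxa))
  stopifnot(length(taxa) >= 1L, length(proportions) == length(taxa),
            abs(sum(proportions) - 1) < 1e-8, all(proportions >= 0),
            all(cdsLenRange >= 2L), all(utrLenRange >= 0L),
            antisenseRate >= 0, antisenseRate <= 1)
  list(taxa = taxa, proportions = proportions,
       nTranscripts = as.integer(nTranscripts),
       cdsLenRange = as.integer(cdsLenRange),
       utrLenRange = as.integer(utrLenRange),
       antisenseRate = antisenseRate, codeId = as.character(codeId),
       seed = as.integer(seed))
}

#' Simulate a multi-taxon transcriptome with a truth table
#'
#' Each transcript is a 5' UTR, one CDS sampled from its taxon's codon
#' usage (ATG start, terminal stop of the active code), and a 3' UTR;
#' with probability `antisenseRate` the whole transcript is emitted
#' reverse-complemented. Each 5' UTR terminates with an in-frame stop codon
#' immediately upstream of the CDS start, so the planted CDS is the maximal
#' complete ORF in its own frame and the truth table names a unique
#' recoverable answer. The truth table records each transcript's taxon,
#' planted reading frame and forward-strand CDS coordinates; the companion
#' reference proteome holds every CDS translation. Byte-identical outputs
#' are reproduced by the same configuration and seed.
#'
#' @param config from [simulationConfig()].
#' @return list: `transcripts` (`DNAStringSet`), `truth` (data.frame:
#'   `transcript_id`, `taxon`, `frame`, `cds_start`, `cds_end`),
#'   `proteome` (`AAStringSet`, one entry per transcript, named
#'   `<transcript_id>_p`).
#' @export
simulateTranscriptome <- function(config) {
  code <- geneticCode(config$codeId)
  taxonNames <- vapply(config$taxa, function(m) m@name, character(1))
  withSeed(config$seed, {
    n <- config$nTranscripts
    taxonIdx <- sample(length(config$taxa), n, replace = TRUE,
                       prob = config$proportions)
    seqs <- character(n)
    truth <- vector("list", n)
    prots <- character(n)
    for (i in seq_len(n)) {
      m <- config$taxa[[taxonIdx[i]]]
      nCod <- sample(seq(config$cdsLenRange[1], config$cdsLenRange[2]), 1L)
      u5 <- sample(seq(config$utrLenRange[1], config$utrLenRange[2]), 1L)
      u3 <- sample(seq(config$utrLenRange[1], config$utrLenRange[2]), 1L)
      cds <- sampleCds(m, nCod, code)
      # terminate the 5' UTR with an in-frame stop so the planted CDS is
      # the maximal complete ORF in its frame: the truth table then names
      # a unique recoverable answer (otherwise chance upstream in-frame
      # AUGs extend the called ORF past the planted start)
      utr5 <- sampleUtr(m, u5)
      guard <- names(code)[unname(code) == "*"][1]
      if (u5 >= 3L)
        utr5 <- paste0(substr(utr5, 1L, u5 - 3L), guard)
      tx <- paste0(utr5, cds, sampleUtr(m, u3))
      cdsStart <- u5 + 1L
      cdsEnd <- u5 + nchar(cds)
      frame <- ((cdsStart - 1L) %% 3L) + 1L
      L <- nchar(tx)
      if (config$antisenseRate > 0 && runif(1) < config$antisenseRate) {
        tx <- revcompChr(tx)
        tmp <- cdsStart
        cdsStart <- L - cdsEnd + 1L
        cdsEnd <- L - tmp + 1L
        frame <- -(((L - cdsEnd) %% 3L) + 1L)
      }
      seqs[i] <- tx
      prots[i] <- sub("\\*$", "", translateSeq(cds, code))
      truth[[i]] <- data.frame(
        transcript_id = sprintf("tx%05d", i),
        taxon = taxonNames[taxonIdx[i]], frame = frame,
        cds_start = cdsStart, cds_end = cdsEnd, stringsAsFactors = FALSE)
    }
    transcripts <- Biostrings::DNAStringSet(seqs)
    names(transcripts) <- sprintf("tx%05d", seq_len(n))
    proteome <- Biostrings::AAStringSet(prots)
    names(proteome) <- sprintf("tx%05d_p", seq_len(n))
    list(transcripts = transcripts, truth = do.call(rbind, truth),
         proteome = proteome)
  })
}

#' Simulate labelled ORF pools for classification tests
#'
#' Emits bare in-frame CDSs (no UTRs) from each taxon with taxon labels,
#' the substrate for decontamination experiments that skip the
#' ORF-prediction stage.
#'
#' @param taxa list of [TaxonModel-class] objects.
#' @param nPerTaxon integer count per taxon (recycled or per-taxon vector).
#' @param lenRange CDS length range in sense codons.
#' @param codeId genetic-code table id.
#' @param seed integer seed.
#' @return list: `orfs` (named `DNAStringSet`), `labels` (data.frame:
#'   `orf_id`, `label`).
#' @export
simulateClassifiedOrfs <- function(taxa, nPerTaxon, lenRange = c(100L, 400L),
                                   codeId = "1", seed = 1L) {
  stopifnot(length(taxa) >= 2L)
  nPerTaxon <- rep_len(as.integer(nPerTaxon), length(taxa))
  code <- geneticCode(codeId)
  withSeed(seed, {
    seqs <- character(0); labels <- character(0)
    for (t in seq_along(taxa)) {
      m <- taxa[[t]]
      for (i in seq_len(nPerTaxon[t])) {
        nCod <- sample(seq(lenRange[1], lenRange[2]), 1L)
        seqs <- c(seqs, sampleCds(m, nCod, code))
        labels <- c(labels, m@name)
      }
    }
    orfs <- Biostrings::DNAStringSet(seqs)
    names(orfs) <- sprintf("orf%05d", seq_along(seqs))
    list(orfs = orfs,
         labels = data.frame(orf_id = names(orfs), label = labels,
                             stringsAsFactors = FALSE))
  })
}

#' Write a simulation to disk
#'
#' @param sim list from [simulateTranscriptome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeFasta(sim$transcripts, file.path(dir, "transcripts.fasta"))
  writeFasta(sim$proteome, file.path(dir, "proteome.fasta"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
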