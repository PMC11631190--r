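# package-level constants (this file loads first)

# fixed 64-codon vocabulary, lexicographic (AAA ... TTT); this order is the
# feature contract shared by tokenizer, classifier and model archive
CODON_VOCABULARY <- sort(as.vector(outer(
  outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
        function(a, b) paste0(a, b)),
  c("A", "C", "G", "T"), paste0)))

DNA_BASES <- c("A", "C", "G", "T")

# standard genetic code as a plain named vector, for hot inner loops
GENCODE1 <- Biostrings::getGeneticCode("1")[
  sort(as.vector(outer(
    outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
          function(a, b) paste0(a, b)),
    c("A", "C", "G", "T"), paste0)))]

# default start codons; alternative starts are configurable off per contract
START_CODONS <- "ATG"

# archive format version for saved classifier models
MODEL_FORMAT_VERSION <- "1"
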