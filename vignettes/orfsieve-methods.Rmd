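---
title: "ORFsieve: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ORFsieve: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and what its validation on synthetic data does
and does not demonstrate.

## Workflow overview

ORFsieve has two modes built on one classifier.

**Prediction** takes a nucleotide assembly and a reference proteome and
returns one ORF per transcript. Stages: (1) length filter; (2) optional rRNA
screen and redundant-isoform clustering; (3) exhaustive complete-ORF
enumeration in all six reading orientations under the chosen genetic code;
(4) translated search of the transcripts against the reference proteome;
(5) training-set construction from the hits; (6) RBF-SVC training on codon
counts; (7) scoring of every candidate ORF and per-transcript selection of
the highest in-frame probability.

**Classification** (decontamination) takes a FASTA of ORFs plus a small
table of user-assigned class labels (or a sample of labels from an external
taxonomic classifier) and assigns every remaining ORF a class with
per-class probabilities.

## ORF enumeration semantics

Coordinates are 1-based inclusive on the forward strand of the transcript;
the sign of the frame (±1, ±2, ±3) encodes the strand, and negative-frame
sequences are reverse complements of the forward-strand slice. Within each
frame the codon stream is segmented at stop codons; the complete ORF of a
segment runs from the *first* ATG after the previous stop through the
segment's stop (the stop codon is included in the nucleotide sequence,
excluded from the translation). Only ATG is accepted as a start by default;
alternative starts can be supplied but are off because none of the supported
use cases requires them. With partials enabled, stop-bounded segments that
contain no ATG are reported whole, as is the trailing stretch of each frame
that reaches the transcript edge without a stop; neither requires a start
codon, which is this package's formalization of a partial ORF.

Default minimum ORF length is 150 nt (50 codons) — short enough to keep
real small proteins, long enough that random open stretches are rare; the
minimum transcript length default is 300 nt. Both are explicit parameters.

Genetic-code tables come from Biostrings; tables 29 (TAA/TAG = Tyr) and 30
(TAA/TAG = Glu), absent from Biostrings 2.70, are defined in-package from
the NCBI definitions. Under table 6 (ciliate), TAA/TAG are sense codons and
enumeration reads through them, which is the difference that lets
read-through CDSs be recovered full length.

## First-stage filters

The rRNA screen's internal backend flags a transcript when at least 25% of
its 31-mers (either strand) occur in a user-supplied rRNA reference; k-mers
containing non-ACGT characters never match. 31 is long enough that chance
matches are negligible and short enough that a couple of percent sequence
divergence still leaves most k-mers intact (at 2% point mutations the
expected intact fraction is 0.98^31 ≈ 0.53, comfortably above the 0.25
threshold). An adapter to Barrnap (all four kingdom models) exists for
production use and raises an explicit error when the program is absent.

Isoform clustering is greedy longest-first (ties broken lexicographically by
id) in the CD-HIT-EST style with the parameter triple: local identity
≥ 0.97, alignment covering 100% of the shorter and ≥ 0.5% of the longer
sequence. A candidate prefilter requires at least 3 shared 20-mers (the
representative index is strided, the query is not) before a banded local
alignment is attempted; near-identical isoforms share hundreds of such
words, so the prefilter only skips pairs that could not pass the identity
threshold anyway.

## Homology-seeded training

The translated search reports at most one hit per transcript at e-value
≤ 1e-30. The internal backend translates all six frames, seeds on exact
5-residue words (at least 8 distinct shared words before alignment — an
exact 50-aa match shares ~46), extends with a BLOSUM62 local alignment
(gap open 11, extend 1), keeps alignments with ≥ 60% identity over ≥ 50
residues, and converts scores to bits with Karlin–Altschul constants
(λ = 0.267, K = 0.041 for gapped BLOSUM62), so an exact 50-aa match always
clears the default e-value cut. A DIAMOND adapter provides the production
path when the binary is available.

Each hit's aligned region, read in the hit's frame and trimmed to a codon
multiple, is an in-frame positive. Each positive is paired with exactly one
out-of-frame negative: the *same* span re-read in one of the five
non-coding orientations (+2, +3, −1, −2, −3), drawn uniformly under the run
seed. Reusing the positive's own span (rather than a random region) keeps
the negative matched for length and base composition, so the classifier
must learn frame structure rather than incidental covariates. One negative
per positive keeps the training set balanced by construction.

## The classifier

Features are raw in-frame codon counts over the fixed 64-codon vocabulary.
Raw counts (not frequencies) are the default because the tokenization
contract is counts; a `normalizeLength` flag exists because RBF distances
on raw counts partly encode ORF length, which is occasionally unwanted.

The kernel is RBF with the data-dependent default
γ = 1/(64 · Var(X)) computed over all feature entries — the standard
"scale" heuristic, which keeps kernel distances O(1) across the wide
dynamic range of count features. Only the cost C is searched: 25 log-uniform
draws from [1e-8, 10] under the run seed, each scored by stratified 5-fold
cross-validated accuracy. **Ties resolve to the largest C.** This matters:
on cleanly separable data every candidate cost reaches CV accuracy 1.0, and
at C ≈ 1e-8 every dual coefficient sits at the bound so decision values have
magnitude ~1e-10 — sign-based accuracy survives, but a sigmoid fitted to
values at that scale is numerically degenerate and argmax-probability
predictions collapse to one class. The hard-margin end of the tie gives
decision values at a calibratable scale.

Probabilities are computed in-package: for each class pair a binary SVM is
fitted (libsvm via e1071, which is deterministic for a fixed dataset), a
Platt sigmoid is fitted by the regularized Newton method to decision values
collected from a seeded stratified 5-fold cross-validation within the pair,
and the pairwise probabilities are coupled into a simplex by the standard
iterative pairwise-coupling scheme. Doing calibration in-package rather
than delegating it has two reasons: libsvm's internal calibration permutes
data with an unseeded PRNG, so identical fits give different sigmoids
within one session, violating the package's determinism contract; and a
model whose prediction path is fully specified by stored numeric arrays can
be archived and reloaded with bit-identical behavior.

The model archive is a single JSON document: metadata (classes, codon
vocabulary, genetic-code table, seed, training hash, versions) plus all
numeric arrays printed at 17 significant digits, which round-trips IEEE
doubles exactly. Nothing executable is stored; loading a truncated or
mismatched archive is an explicit error.

Training warns below 25 examples per class — the recommended minimum —
and errors below 2. Per-transcript selection takes the candidate with the
highest in-frame probability; exact ties go to the longer ORF, then the
smaller start coordinate, then the positive strand. Identical inputs and
seed give bit-identical models and predictions; predictions are also
independent of how queries are batched at the level of predicted labels and
probabilities to ~1e-15 (BLAS blocking can perturb the last bits across
different batch shapes, which is why bit-identity is guaranteed within a
call and across save/load round trips, not across arbitrary re-batchings).

## Composition metrics

GC12 is the percent G+C across codon positions 1 and 2; GC3 across position
3; GC3s restricts GC3 to four-fold degenerate codons, i.e. codons whose
amino acid is unchanged by any third-position substitution *under the
active code table* (so table 6 shifts the degenerate set correctly). Codons
containing non-ACGT characters are excluded from every tally, and GC3s is
undefined (NA) for sequences with no four-fold codon. For six-codon families
(Leu, Arg, Ser) the four-fold subfamily counts toward GC3s and the two-fold
subfamily does not; this is an interpretation choice, flagged here because
published GC3s definitions vary.

Composition-window selection (`selectByComposition`) is inclusive on both
bounds. Published composition-cluster thresholds mix inclusive ("35% to
45%") and strict ("45% < GC12 < 55%") notation; we standardize on inclusive
because window bounds are user-chosen round numbers and boundary ORFs are
rare enough that the choice is immaterial in practice.

## Decontamination workflow

The class table is a two-column TSV (`orf_id`, `label`), `#` comments
allowed, labels free strings; at least two classes, no conflicting
duplicates, and all ids must exist in the query FASTA. Labels from an
external taxonomic classifier are subsampled to at most 100 per category;
categories with fewer than 25 available sequences are dropped with a
warning (25 is the minimum training size, 100 the point of diminishing
returns on the synthetic regimes below). Training ORFs are echoed in the
output flagged `training = TRUE` and are excluded from any scoring; every
ORF is assigned its argmax class — there is no "unclassified" threshold,
because the per-class probabilities are reported and the user can impose
any cutoff downstream.

## The synthetic-data generator

The generator is first-class, tested code: it is the substrate for every
end-to-end claim the package makes about itself.

A taxon model is a codon-usage vector constructed so that the expected
third-position GC of sampled sense codons equals the target exactly: the
four third-base classes receive probability g/2, g/2, (1−g)/2, (1−g)/2
(G, C, A, T), distributed over each class's non-stop codons. Within-class
weights interpolate between a shared Dirichlet draw (common to all taxa)
and an independent one: divergence 0 reproduces the shared usage exactly
("identical" fingerprints), divergence 1 gives independent fingerprints
("distinct"), and the package uses 0.05 as its "near-identical" regime —
enough residual signal that more training data helps, little enough that
25 examples per class sit near chance.

A transcript is 5′UTR + CDS + 3′UTR, reverse-complemented with a
configurable probability; UTR bases are i.i.d. (uniform by default), CDS
codons are drawn from the taxon usage between a forced ATG and a terminal
stop of the active code. Each 5′UTR ends with an in-frame stop codon
immediately upstream of the CDS: without this guard, roughly one transcript
in five carries a chance upstream in-frame AUG with no intervening stop, the
first-ATG enumeration rule then yields an ORF strictly containing the
planted CDS, and the truth table no longer names an answer any caller could
recover — full-length recovery saturates near 82% for reasons unrelated to
the method. The guard makes the planted CDS the maximal complete ORF in its
frame, so recovery metrics measure the pipeline rather than fixture
ambiguity.

What the generator does **not** model: realistic UTR composition and
untranslated ORFs, splice isoforms, sequencing error, coverage-dependent
assembly artifacts, chimeras, and read-level simulation (the in-silico
mixtures are built at transcript level). Passing the package's synthetic
checks therefore demonstrates correctness of the algorithms under clean
composition signals, not performance on any particular real library.

## Validation design and problem sizes

The package validates itself at these scales, chosen to exercise every code
path while staying comfortably fast on one CPU: six-frame enumeration
against an independent full-translation/regex scanner on 1,000 random 2-kb
transcripts under tables 1 and 6 (exact equality); end-to-end prediction on
a 500-transcript single-taxon simulation (≥95% planted-frame recovery,
≥90% full-length recovery under the 98/98 rule); two-taxon decontamination
over 20 seeded replicates per condition — distinct fingerprints at mixing
ratios 50:50 through 80:20 with 25 training ORFs per class (≥95% held-out
accuracy), near-identical fingerprints across training sizes 25/100/200 drawn from
300-ORF-per-class pools (non-decreasing mean held-out accuracy), and a
90:10 near-identical mixture where minority-class recall is tested for
statistical compatibility with chance; and a three-taxon mixture at
proportions 0.64/0.11/0.25 with 100 training ORFs per class (macro-F1
≥ 0.90).

"Compatible with chance" is operationalized per replicate: an exact
binomial test of the minority-class recall against 0.5 must fail to reject
in at least half of the replicates ("often approximates chance"), and the
mean recall must stay within two per-replicate chance standard deviations
of 0.5. A pooled zero-association test would be the wrong instrument here:
the near-identical regime is built with a small nonzero divergence
(otherwise more training data could not help), so with enough replicates
any pooled point-null test rejects on an effect of a few percentage
points — the claim being validated is that a typical run is
indistinguishable from coin-flipping, not that the effect is exactly zero.

## Known limitations

* The internal translated-search and clustering backends are deliberately
  simplified re-implementations adequate for fixtures and small runs;
  production-scale datasets should use the DIAMOND / CD-HIT-EST / Barrnap
  adapters.
* E-values from the internal backend are Karlin–Altschul approximations,
  not BLAST-calibrated.
* Codon-count features carry length signal unless `normalizeLength` is set;
  with very heterogeneous ORF lengths and weak composition differences this
  can dominate the kernel.
* No probability threshold marks ORFs "unclassified"; downstream filtering
  is the user's choice.
* Selection returns exactly one ORF per transcript; polycistronic or
  chimeric transcripts are outside the model.
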