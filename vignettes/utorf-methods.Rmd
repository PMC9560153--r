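---
title: "Methods: from genome to unannotated translated ORFs and their evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from genome to unannotated translated ORFs and their evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfevo)
```

## The problem

Shotgun mass spectrometry can only identify proteins it is told to look for.
Lineage-specific proteins — in particular de novo genes, born from
previously nongenic sequence — are systematically under-annotated, so a
standard search against the annotated proteome cannot find them. `orfevo`
implements a proteome-first route around this: build the exhaustive catalogue
of *potential ORFs* (every stop-free codon span in all six frames of the
genome and transcriptome), screen peptide-spectrum matches (PSMs) against it
with a two-round target-decoy strategy, and then characterize the surviving
unannotated translated ORFs (utORFs) comparatively: how old is each locus,
is its conservation pattern consistent with de novo birth, how often has it
been lost again, what latent subpopulations exist, and which loci deserve
experimental follow-up.

Every stage is exercised on synthetic data with planted ground truth, so the
whole pipeline is testable offline.

## Potential-ORF cataloguing

A potential ORF is a maximal contiguous span of amino-acid-coding codons —
deliberately *not* required to start with ATG, because a six-frame
translation cannot reassemble spliced exons, and no internal coding exon
contains a stop codon. Spans are broken at stop codons (TAA/TAG/TGA,
standard nuclear code) and at codons containing `N` or a soft-masked
(lowercase) base; working from the repeat-masked genome keeps transposable
elements and other degenerate repeats out of the catalogue. Retention rules:
at least 8 residues, and at least 20 residues for spans containing no
in-frame ATG-encoded methionine ("containing", not "beginning with"; the
offset of the first start is recorded for length-after-start statistics).
The length rules are applied per ORF, before deduplication, which is exact
amino-acid string equality with all genomic occurrences preserved.

Coordinates are 0-based, half-open, with reverse-frame spans stored in
forward-strand coordinates (BED-compatible). Mitochondrial contigs use a
different genetic code and should not be passed through the nuclear
enumerator.

## Two-round PSM screening

The potential-ORF database is several orders of magnitude larger than the
annotated proteome, so a single search at a strict false discovery rate
(FDR) has very little power. The two-round strategy first runs a permissive
*discovery* round (FDR 0.2) against the full candidate database purely to
shrink it, then a strict *verification* round (FDR 0.01) against the
survivors plus the annotated proteome, at both the peptide level and the
protein-group level (group scores are the best PSM per group; the group FDR
is computed jointly with annotated groups by default, restrictable via
`group_scope`).

FDR estimation is the plain target-decoy ratio `#decoys >= s / #targets >= s`
with q-values as the running minimum from worst to best score; ties at a
threshold count decoys first. We use `d/t` rather than `(d+1)/t` to match
the convention of the upstream search engines; the calibration tests show
the small threshold-selection bias this carries (realized FDR ~0.011 at
nominal 0.01 for a single round) and that the full two-round selection is
strongly conservative (realized ~0.003 at nominal 0.01).

Post-verification curation drops candidates shorter than 14 residues, drops
candidates carrying an externally supplied homology flag (homology searches
themselves are out of scope), and keeps only the longest candidate per
protein group. The retention-time filter marks a candidate peptide supported
when at least one of its PSMs has `|observed - predicted RT|` at or below
the 95th percentile of the deltas of all annotated-protein PSMs (quantile
type 7, linear interpolation — documented and fixed; one global threshold
across runs).

Polymorphism screening asks whether a "novel" peptide could be a population
variant of an annotated peptide: all tryptic peptides (cleavage after K/R
except before P, up to 2 missed cleavages, minimum length 7) are indexed in
a prefix tree, and each candidate peptide is queried for its minimum Hamming
and Levenshtein distance with branch-and-bound pruning at a small cap.
Isoleucine and leucine are kept distinct.

## Synteny-anchored protein similarity

Whole-genome homology search is both heuristic and context-blind; for short,
fast-evolving loci it misses true orthologs. Instead, the orthologous
sequence of each locus is taken directly from a whole-genome multiple
alignment: the blocks covering the locus plus 9 bp of flank on each side are
sliced and stitched on reference coordinates. Species absent from every
covering block are *missing* (never evidence of anything); species present
in some blocks are gap-filled across the others. Genomic identity is
computed on shared non-gap columns, and coverage (species non-gap columns /
reference non-gap columns) at or above 0.5 sets the genomic homology flag
(the alternative — re-aligning after gap dropping — is noted but not used).

The protein similarity score aligns the reference protein against the
three forward-frame translations of the species' degapped block sequence
(alignment rows are orientation-consistent, so no reverse complement),
using Smith–Waterman local alignment with BLOSUM62 substitution scores and
**zero** gap open/extension penalties, normalized by the reference ORF
length, keeping the best frame. Free gaps and the three-frame maximum make
the score robust to small indels and recent frameshifts; stop codons are
retained as `*` and scored -4 against everything (the BLOSUM62 minimum), so
recent nonsense mutations penalize but do not truncate the alignment. The
flanks are included in the translated sequence — with a local alignment they
can only help.

### The null model and the 2.5-point threshold

Significance is calibrated against random sequence: 10,000 pairs of random
amino-acid sequences, residues i.i.d. from an embedded fruit-fly
proteome-composition table, lengths uniform on 20–150. One length is drawn
per pair and used for both members. This is a deliberate design choice: the
score is normalized by the first (reference) sequence's length, so pairing a
short reference with a long partner mechanically inflates the normalized
score, and drawing the two lengths independently mixes those inflated pairs
into the pooled summary (pooled mean ~2.0 and SD ~0.74 instead of ~1.94 and
~0.16). With equal-length pairs the expected score runs from about 1.7 (20
residues) to about 2.0 (150 residues) and the pooled mean plus two SDs stays
below 2.5 — which is why 2.5 points is a conservative significance
threshold. The threshold is a fixed input, never re-derived from the
simulation. `calibrate_null(pair_lengths = "independent")` exposes the other
variant.

## Age, de novo origin, and loss

Phylostratigraphy: the inferred origin of a locus is the last common
ancestor of the reference species and the most distantly diverging species
with score > 2.5. Strata are topological ranks along the reference's
root path (0 = reference-specific), not absolute ages; ties between equally
distant significant species are resolved by taking the LCA over all of them.
Monophyly compares the significant set against the *data-bearing* leaves of
the subtree at its LCA, so species without alignment data cannot break it.

A locus is called potentially de novo when at least two outgroup species
(outside the origin clade), from at least two distinct first-branching
outgroup lineages, have genomic homology (coverage flag) but score below
threshold: the DNA was there, a similar protein was not. Requiring two
independent lineages guards against single homology-detection failures; the
"different phyla" notion is interpreted topologically since all species in
such trees are insects.

Losses after origin are counted by Dollo parsimony (one birth, losses only):
among species descended from the origin, *lost* means homologous-but-
nonsignificant, *present* means significant, anything else is *unknown* and
never forces an event. The minimum number of loss events is the number of
maximal subtrees whose data-bearing leaves are all lost; the implementation
is a single post-order pass, verified against exhaustive subtree-cover
search on the eight-leaf test tree.

The length-matched empirical null (used for secondary-structure-style
metrics) draws 250 control loci of identical length per locus (widening the
tolerance over 0, 1, 2, 5, 10, 20, 50 length units when a bin is thin),
takes the midrank percentile floored at `1/(n+1)`, and combines loci with
Fisher's method against a chi-square with `2k` degrees of freedom.

## Latent class analysis

Locus features are binned into categorical indicators (phastCons
`[0,0.2)/[0.2,0.8)/[0.8,1]`, length `[0,20)/[20,50)/[50,Inf)` residues,
transcription at max TPM > 0.1, specificity at tau > 0.8; all interior
boundaries half-open on the right so that touching bin edges are
unambiguous).
Rows with any missing indicator are excluded before fitting.

The latent class model — a finite mixture of independent categorical
distributions — is fitted by EM from 100 random restarts, each run to
convergence (the common repeated-estimation idiom); restarts initialize
conditionals from a flat Dirichlet with uniform mixing, and the best
log-likelihood wins. Restarts
that tie at the top log-likelihood with materially different parameters are
counted as distinct optima: such a K is under-identified and is excluded
from model selection, which otherwise takes the smallest BIC (AIC agreement
reported). Classes are relabeled by decreasing mixing proportion; posterior
assignment is exact Bayes with ties going to the lowest class index.
Conditional probabilities are floored at 1e-12 for numerical safety, which
perturbs the K = 1 closed form (observed marginals) at far below test
tolerance.

## Expression and ribosome-profiling support

Specificity is tau, `sum(1 - x/max(x)) / (N - 1)`, on linear TPM by default
(a log variant is available; the choice is ambiguous in common usage).
Transcription support is max TPM strictly greater than 0.2. Contrasts are
`log10(TPM + 0.01)` differences (pseudocount documented, 0.01). Framing
uses the one-sided upper binomial tail `P(X >= n0)` with `p = 1/3` on
footprints pooled across replicates and read lengths; loci need strictly
more than 2 unique footprints (the operational definition; "at least two"
also circulates — the minimum is configurable). Because the binomial test is
discrete it is conservative: at nominal alpha 0.05 its exact null rejection
probability, averaged over realistic footprint depths, is ~0.04. The
calibration test therefore compares the empirical type-I rate against the
exactly computed discrete level rather than against 0.05 itself.
Prioritization averages per-factor midranks (best = 1) with declared
better-directions; it is invariant to monotone transforms of any factor.

## The synthetic-data generators

`simulate_msa_loci()` plants an ORF (ATG start, stop-free, terminal stop,
30–80 residues, 30 bp flanks) at the root of an eight-taxon fly-like tree
and evolves it with Jukes–Cantor-like substitutions and geometric-length
deletions (deletions are the only indels, so alignment columns are stable).
Protected coding spans evolve at 0.2 of the neutral rate with nonsense
substitutions reverted and deletions excluded — an explicit model of
purifying selection; without it "conserved" loci would diverge beyond
recognition over outgroup branch lengths. De novo birth is modeled by
placing a codon-shuffled (composition-preserving, alignable, protein-
destroying) version of the ORF at the root and the coding version on the
branch entering the origin clade; loss by codon-shuffling plus two nonsense
codons on the lost terminal branch. The tree has two successively branching
outgroups precisely so that planted de novo loci satisfy the two-lineage
support rule.

What the generators do *not* emulate: codon models or selection
coefficients, insertions, alignment error, spectra (PSM scores are drawn
directly from shifted/null normal mixtures with decoys matching false
targets one-for-one), and the correlation structure of real locus features
(the latent-class table is drawn from the generating model itself). Passing
tests therefore demonstrate that the algorithms recover what was planted
under their own assumptions — not that real fly data would behave as
cleanly.

## Problem sizes and runtimes

The bundled tests run the null calibration at the full 10,000 pairs (three
seeds), oracle equivalences at 1,000 random alignment cases, 500 random
loss profiles and all footprint triples up to n = 12, FDR calibration over
20 seeds, latent-class recovery at n = 2,000 with model selection over
K = 1..5 across 20 seeds, and the end-to-end pipeline at 40 loci. The
pipeline default is 60 loci with 100 EM restarts; `run_end_to_end()` on
those defaults takes on the order of a minute on one core.

## Known limitations

* Age calls depend on alignment quality; the package treats the input MSA
  as ground truth and cannot detect misalignment.
* The de novo call is conservative by construction (two independent
  homologous-but-nonsignificant lineages); loci with sparse outgroup
  coverage are never called de novo rather than called with low confidence.
* Dollo loss counts are minima, and merge planted sister losses into one
  event when the data cannot distinguish them.
* The d/t FDR estimator is slightly anti-conservative at a fixed q cutoff;
  users needing strict control can use the two-round selection, which is
  conservative overall.
* The latent-class EM can be under-identified for K near the number of
  distinct response patterns; `select_classes()` excludes such K rather
  than guessing.
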