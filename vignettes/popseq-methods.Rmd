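---
title: "Methods: profiling overlapping sorted cell populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling overlapping sorted cell populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popseq)
```

## The measurement model

popseq analyses RNA-seq of flow-sorted cell fractions whose memberships
*overlap* rather than partition an embryo. Each fluorescent reporter strain
yields a positive and (usually) a matched negative fraction; because many
reporters label unions of lineage clades, a cell is typically captured by
several fractions. The analysis treats each measured fraction as a purity-
weighted mixture of its member cells and of the contaminating complement:

    sample(g) = purity * mean(member cells) + (1 - purity) * mean(complement)

Sort purities in such experiments are measured by re-sorting, typically
0.82-0.97; the simulator defaults to 0.9.

### Quantification and enrichment

Counts are normalized to reads per million over non-excluded genes
(ribosomal and mitochondrial RNA excluded from the denominator by default,
but still reported against it). Differential signal per experiment is the
pseudocounted log-ratio

    E(g) = log2( (c + RPM_pos(g)) / (c + RPM_ctrl(g)) ),   c = 3 RPM

with the control named by each experiment's policy: the matched negative
fraction, the singlet sample (for sorts without a matched negative; since any
gated fraction is a subset of the singlets this understates the true
enrichment, and such columns are flagged conservative), or the
double-negative sample of a two-reporter strain. The pseudocount of 3 RPM
bounds the enrichment of genes with few reads; a gene absent from both
fractions scores exactly 0. Genes are called enriched/depleted at |E| >= 2
(a 4-fold linear change); the boundary is inclusive so that "cutoff 2 means
4-fold" stays literally true.

Replicate call accuracy is defined as: among genes called in replicate A, the
fraction whose enrichment in replicate B has the same sign. B is thresholded
at zero by default - the weakest reading of "predicting the direction in a
replicate" - and a stricter B cutoff is an argument.

### Singlet gating

Forward/side-scatter singlet gating depletes cell types that clump. The
simulator plants this bias by over-weighting one designated tissue 3x in the
ungated sample (the magnitude is a free simulator parameter; no measured
value exists for it, so it is simply a plausible, clearly visible bias). Two
consequences are analysed: the singlet-vs-ungated enrichment column (appended
to the matrix as a pseudo-experiment so clustering can see gating-biased
genes), and `reconstruction_check()`, which asks whether rescaling the
ungated profile by the pseudocounted singlet/ungated ratio improves the
correlation between each experiment's recombined positive+negative profile
and the ungated sample (one-sided paired Wilcoxon across experiments). The
combination weight per experiment is the fraction of cells that are positive,
taken from the sort scheme, since the true mixing weight of a sort is not
otherwise observable.

## Coexpression clustering

Gene enrichment profiles are clustered with complete linkage on correlation
distance (1 - Pearson r) and cut either at a height or to an exact cluster
count. Zero-variance (all-equal) profiles have no defined correlation and are
excluded with a warning; they are non-differential by construction and are
reported separately. Agglomeration uses `stats::hclust`, which is
deterministic given the input order; a permutation test in the suite checks
memberships do not depend on row order. Centroids are arithmetic means of
member profiles.

Which genes to cluster is a genuinely open choice. The pipeline default
clusters genes detected at >= 1 RPM in >= 1 sample. For parameter-recovery
analyses the package clusters the *called* (>= 4-fold) genes instead: an
unstructured background of ubiquitous and noisy genes merges at the top of a
complete-linkage dendrogram and absorbs clusters when the tree is cut at
exactly the planted pattern count, so recovery is measured where differential
structure exists, and the adjusted Rand index is computed over genes carrying
a planted tissue pattern. `select_cut()` offers the alternative, data-driven
cut selection: it scores candidate cluster counts by how many motif-cluster
enrichments they expose at a q threshold and returns the argmax (ties to the
smaller count).

Cluster specificity flags use two strict (>) cutoffs: mean over member genes
of log2(1 + max-over-samples RPM) > 4 and mean |enrichment| > 0.2. The
max-sample convention defines "expression" of a gene as its level in the
sample where it is highest, matching how detection is defined.

## Set, motif and ChIP enrichment

All set enrichment is the upper-tail hypergeometric probability P[X >= k]
with Benjamini-Hochberg correction applied within each analysis call (one
family per term-collection x target-collection; no global family is defined).
The universe defaults to genes detected at >= 1 RPM in >= 1 sample, which
avoids inflating folds with never-observed genes.

### PWM scanning with exact p-values

Motif scanning is implemented in the package. Scores are log2 odds against
the motif's background, with a probability floor of 1e-3 added to matrix
entries (then renormalized) so log-odds stay finite. Score significance is
exact, not asymptotic: per-position scores are quantized onto a common
integer grid (1e4 bins across the score range) and the null distribution of
the total quantized score over i.i.d. background sequence is built by
dynamic-programming convolution across positions. Observed windows are scored
with the same quantized matrix, so the DP tail probability is exact for the
statistic actually used - the suite verifies equality with brute-force
enumeration over all 4^L words up to L = 8. Both strands are scanned (the
reverse strand via the reverse-complement matrix; backgrounds are
strand-symmetric), windows containing N are skipped, and a hit's distance is
counted from its TSS-proximal edge to the TSS (the promoter's 3' end), so a
window ending at the last base has distance 1.

### The cutoff grid

Hits are dichotomized into per-gene presence over a grid of upstream
distances (1, 2, 3 kb), minimum mean conservation over the window (0, 0.5,
0.7, 0.9) and minimum score in -10*log10(p) units (30, 35, 40, i.e. p <=
1e-3, 10^-3.5, 1e-4; the base of the published "log p score" convention is
ambiguous, so the grid is configurable). Presence is antitone in every
cutoff. The hypergeometric test counts genes with presence, not raw
occurrences, because draws-without-replacement is defined over genes. BH runs
jointly across all motif x cluster x grid-cell tests (conservative), and each
motif-cluster pair reports its minimum-p cell; per-cell results remain
available as an attribute. ChIP-peak enrichment reuses the machinery with the
distance axis only. Motif redundancy is collapsed before testing:
similarity is the best mean per-aligned-column Pearson correlation over
ungapped offsets and both orientations (>= 4 aligned columns), single-linkage
clustered at PCC distance < 0.01, keeping the lexicographically first id.

Candidate regulators are TFs whose own enrichment profile correlates with a
cluster centroid above r = 0.7 and whose motif is enriched in that cluster
below q = 0.001. Positional/conservation bias of a motif's instances inside
versus outside a cluster uses two-sided Mann-Whitney tests with the direction
taken from the median difference.

## Per-cell deconvolution

The membership matrix has one row per experiment and one column per terminal
cell: `purity * 1[members]/|members| + (1-purity) * 1[complement]/|complement|`,
so rows sum to one; double-gated quadrants use set algebra on the two marker
memberships. Per gene, the estimate is the Moore-Penrose pseudoinverse of the
membership applied to the linear fold-enrichment vector (2^E) - the
minimum-norm least-squares solution, with no nonnegativity constraint (a
clipped variant would be an extension, not the default). Rank and condition
number are reported. Columns default to terminal cells, which is heavily
underdetermined for realistic schemes; `tissues=` aggregates columns to
condition the problem when wanted.

Leave-one-out cross-validation refits without each experiment and predicts
its values from the held-out membership row; designated experiments (the
double-positive sort, by convention) are predicted but never fitted. Two
properties are exercised: predicting the double-positive (+/+) quadrant is
systematically harder than the single-positive (+/-, -/+) quadrants, because
the overlap cells are constrained only indirectly; and mean LOO r rises with
the number of distinct single-marker fractions (8 -> 16 -> 32), the
identifiability argument for dense fraction panels. The fraction-count
analysis uses single-marker schemes only: a one-to-three-cell double-positive
row otherwise dominates the fits and obscures the comparison.

## The synthetic embryo

The generator provides every input with known truth:

* **Lineage**: a random binary tree; divisions follow a steady clock assigned
  in depth-first order, so each clade occupies a contiguous time block and
  tissues (leaf sets of subtrees, largest split first) form successive
  developmental waves. Terminal cells keep an expression window of
  0.4 x total time (400 min by default) after birth.
* **Truth**: genes carry one pattern - a tissue-restricted pattern (fold 16
  in member tissues), ubiquitous (20% of genes), or unstructured noise (5%,
  per-cell lognormal sd 2 log2 units) - times i.i.d. lognormal noise (sd 0.25
  log2 units per entry) and a lineage random walk (sd 0.1 log2 per division)
  that gives sister cells correlated deviations; the walk is kept well below
  the i.i.d. noise so tissue signal dominates. About 2% of genes are lincRNAs
  placed next to a same-pattern coding partner and 1% antisense RNAs
  overlapping their partner on the opposite strand; small rRNA/mito sets
  exercise the RPM exclusion. Each pattern designates one member gene as its
  regulator TF.
* **Markers**: unions of 1-3 subtrees; one subtree per marker comes from a
  partition of the tree so the panel covers every cell, and extras create the
  heavy pairwise overlap that distinguishes this design from disjoint-type
  markers. The double-reporter pair is the valid pair (all four gating
  quadrants nonempty) with the smallest intersection.
* **Counts**: multinomial at fixed depth given the mixture proportions - so
  column sums equal the depth exactly and RPM estimation is noisy without
  overdispersion; contamination is drawn from the complement's mean profile,
  matching re-sort purity semantics.
* **Sequences**: i.i.d. background promoters (GC 0.36) with each pattern's
  motif consensus planted once per target gene at a distance drawn from the
  rule's band, on a random strand; conservation is a low random background
  per gene, elevated to the rule's level over planted windows; ChIP peaks
  (named by the regulator TF) cover planted windows +-50 bp. Decoy motifs are
  drawn to be dissimilar from all other consensi in every ungapped alignment
  and orientation, since a near-duplicate decoy would legitimately rediscover
  planted sites (the redundancy that motif dedup exists to remove). Track
  coordinates are promoter-relative: the "chromosome" is the gene id and the
  TSS sits at the promoter length - valid bedGraph/BED that keeps sequence
  truth self-contained.
* **Time series**: expression of a gene at time t is its summed abundance
  over terminal cells alive at t.

Temporal specificity weights time by the positive part of each gene's
z-scored log temporal profile ("when the gene is enriched relative to its own
baseline"); max-normalized and raw weightings are options. The z-score
strategy is the default because raw expression profiles share the global
live-cell curve, which dilutes tissue timing. The SD cutoff for calling a
gene time-specific is a required analysis parameter; the pipeline uses an
eighth of the time span, just above the SD of a profile confined to a single
cell-lifespan window.

### What the simulation does not emulate

Real genome sequence and real lineage identities; reporter perdurance
kinetics (only a marker-kind label); overdispersed counts (a gene-level
negative-binomial option is the natural extension); batch effects and
amplification bias; isoform structure. Passing recovery tests therefore shows
the algorithms are correct under the stated measurement model, not that the
model captures every artifact of real sorted-population RNA-seq.

## Problem sizes and numerical choices

The test suite runs full-scale clustering recovery (2,000 genes, 500 cells,
12 patterns, 14 markers, depth 2e6, 10 seeds) and moderate-scale studies
(600 genes, 120 cells, 1.2 kb promoters, depth 5e5, 10 seeds) for the motif,
unmixing and gating analyses; the acceptance script uses the same sizes with
5-seed panels. Stochastic direction checks require 8 or 9 successes in 10
seeds. Score quantization uses 1e4 bins; pseudoinverse tolerance follows the
usual `max(dim) * max(singular value) * eps` rule; ties in coexpression
queries break on gene id, and equidistant genomic neighbors resolve toward
the smaller start coordinate. All genomic intervals are 0-based half-open
internally.

## Known limitations

Enrichment ratios are not linear in per-cell expression, so pseudoinverse
unmixing of fold-enrichments is an approximation inherited from the method it
implements; LOO r quantifies how far it carries. Complete-linkage cuts at an
exact cluster count are brittle in the presence of unstructured genes (see
above). The singlet correction assumes the gating bias is expressed
multiplicatively per gene. Hypergeometric tests ignore gene-gene correlation
within clusters, which BH correction does not repair; planted-truth
simulations show the resulting decoy false-positive rate stays below nominal
in this regime, but strongly correlated real data may differ.
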