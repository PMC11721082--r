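---
title: "Classifying giant-virus genomes from protein-family profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying giant-virus genomes from protein-family profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Giant viruses (phylum *Nucleocytoviricota*) recovered from metagenomes
arrive as incomplete, fragmented metagenome-assembled genomes (MAGs).
Marker-gene phylogenetics struggles here: any fixed marker set may be
missing from a 40%-complete bin, and lineages such as *Mirusviricota*
and jumbo phages carry enough giant-virus-like genes to masquerade as
*Nucleocytoviricota*. gvtax instead classifies a genome from a broad
genomic signature: the presence/absence profile of giant virus
orthologous groups (GVOGs, protein families modeled as profile HMMs)
plus GC content, fed to random-forest classifiers trained separately at
the order and the family level.

## The feature model

A genome is represented as a row vector
`(gc_content, x_1, ..., x_p)` with `x_v = 1` iff at least one predicted
protein of the genome hits GVOG `v` with a full-sequence E-value at or
below `1e-10` in an `hmmsearch` against the GVOG profile set.

Choices worth stating:

* **Presence, not counts or bit scores.** Hit multiplicity grows with
  genome completeness and paralog expansion; binary presence is the
  representation least confounded with completeness.
* **Full-sequence E-value, inclusive threshold.** tblout column 5 is
  hmmsearch's primary significance measure; `<=` keeps boundary hits.
  The alternative (best-domain E-value) is a plausible variant but is
  not what hmmsearch ranks by.
* **GC over concatenated contigs** (length-weighted), not the mean of
  per-contig GC values; ambiguity codes are excluded from numerator
  and denominator.
* **Genome size is never a feature**, precisely because the tool must
  work on incomplete genomes.
* Protein ids map to genomes via the Prodigal convention
  (`<contig>_<n>`); the regex is configurable for other gene callers.

## Feature screening and reduction

With thousands of GVOG profiles, most features are rare outside one
lineage. Screening keeps GVOGs whose within-order prevalence reaches
`min_prevalence = 0.25` in at least one order (`mode = "any"`); the
stricter every-order reading is available by configuration. The
any-order default is the one compatible with arriving at a broadly
represented feature set when few genes are shared across all orders.
GC content always survives screening.

Three tools then probe how many features matter:

* **RFE curves** (`rfe_curve()`): iteratively drop the 10% of
  remaining features with the lowest impurity importance (the step
  size is our choice; the elimination schedule is otherwise standard)
  down to each requested size, and score each surviving subset by
  stratified k-fold CV. On real-style data the curve plateaus around
  150 features (order) and 200 (family); those are the defaults for
  the final models, both configurable.
* **Permutation importance** (`permutation_importance()`): mean drop
  in held-out accuracy over `n_repeats = 10` shuffles of one column.
  Binary GVOG profiles are strongly collinear (co-inherited gene
  blocks), and collinearity masks permutation importance: a model can
  route the same signal through a correlated copy, so shuffling one
  copy barely moves accuracy. The remedy implemented: cluster features
  on Spearman rank correlation distance `1 - rho` with Ward linkage
  (`spearman_cluster()`, cut height 0.5 by default; the linkage is
  standard for this use, the cut height is our choice), keep one
  representative per cluster, retrain, and measure importance on the
  reduced set. Constant columns are assigned `rho = 0` against
  everything so they cluster alone rather than poisoning the
  distance matrix.
* **Impurity importance (MDI)** (`impurity_importance()`): mean
  decrease in Gini impurity, normalized to sum to 1. The forest
  backend (ranger) exposes only the aggregate, so the per-tree spread
  is reported as `NA`; rankings are unaffected.

`select_final_features()` takes the top-k by mean importance with
lexicographic tie-breaking and always retains GC content.

## Training

`gv_tune()` implements the two-stage search: a randomized stage over a
broad grid (forest size 100–1000, depth unbounded–50, features per
split sqrt/log2/fractions, minimum node size 1–10, bootstrap on/off),
then an exhaustive grid one step either side of the stage-1 optimum
for numeric parameters. All scoring is stratified k-fold CV accuracy
(default 10 folds; folds are dealt round-robin within class, so every
fold's class counts are within one of proportional). The grid is
phrased in the forest backend's vocabulary: ranger controls leaf
geometry through a single `min.node.size` rather than separate
split/leaf minima.

`gv_nested_cv()` wraps the whole search in an outer CV loop; outer
test folds are never seen by the inner search, which is the property
that makes the outer mean an honest generalization estimate. With a
single-configuration grid the inner loop degenerates and nested CV
coincides exactly with `gv_kfold_cv()` (same fold assignment, same
fit seeds) — a useful identity for testing.

Class imbalance is handled by stratification only; balanced class
weights exist behind `class_weights = "balanced"` but are off by
default, since the realistic failure mode (bias toward the most
populous order) is something users should see, not something silently
reweighted away.

`gv_fit()` freezes the feature and class order into the returned
`gv_classifier`; prediction rejects any feature mismatch by name
rather than silently reordering or imputing. Models persist as a
directory (serialized forest + JSON metadata with a format version);
loading a mismatched version is an error.

Determinism: every stochastic step (fold dealing, subsampling,
randomized search, forest fitting, fragment placement, data
generation) derives its RNG state from an explicit seed, and forests
run single-threaded, so identical inputs and seeds give bit-identical
outputs.

## Fragmentation simulator

Real MAG incompleteness is simulated rather than observed:
`fragmentize()` takes one uniformly placed contiguous window for
single-contig genomes; for multi-contig genomes it shuffles contigs,
accumulates whole contigs until the next would exceed the target
length, and trims the last with a uniform window. This mimics how
binning loses whole contigs while preserving local contiguity. The
mechanics are our design; the completeness targets are drawn uniformly
from per-group bounds (23–99% for giant viruses, 29–99% for the
non-giant-virus group). The augmentation policy is additive over
rules, which is what lets the rare *incertae sedis* genomes receive 6
extra fragments on top of the giant-virus default of 2 — the only
reading consistent with the augmented-set totals the policy reproduces
in the tests.

## AAI module

One-way average amino acid identity: every query protein is aligned
locally (Smith–Waterman, BLOSUM62, gap open 10 / extend 1, via
Biostrings) against every reference protein; the best hit per
(query protein, reference genome) counts if its score reaches
`min_score = 60`, a cutoff that keeps chance local alignments between
unrelated proteins from counting as homologs. The alignment fraction
AF is the percentage of query proteins with a qualifying hit — a
query-side normalization, matching the one-way direction of the
search; an aligned-length variant was considered and rejected because
the floor rule is applied per input genome. AAI is the mean percent
identity of those best hits, and any reference with AF < 20 is
reported as AAI 0 (the raw mean is kept in a side column). Ties at
the best match break by higher AF, then lexicographic genome id.

## What the synthetic generator does and does not emulate

`make_signatures()` + `sample_dataset()` generate the block structure
that makes profile-based classification work: order-level signature
cores shared by the order's families, smaller disjoint
family-specific additions, Bernoulli presence at
`p_signature = 0.9` inside and `p_background = 0.02` outside the
signature, and order-specific GC means spread over 0.25–0.55 with a
per-genome SD of 0.02. Each present GVOG is anchored to a genome
coordinate, so fragmentation genuinely deletes the features whose
loci fall outside retained windows. Decoy tblout lines with E-values
above `1e-10` exercise the significance filter end to end.

The generator does **not** emulate: protein sequence evolution (hits
are declared, not aligned), assembly chimerism or contamination,
correlated presence beyond the block design, phylogenetic
autocorrelation within a class, or realistic genome sizes (synthetic
genomes default to 20 kb across 4 contigs so suites run in seconds —
a scale choice of this package, with signature loci scaled to match).
Consequently, passing the recovery benchmark shows the pipeline
machinery is correct and that signature-structured data of this
separation is recoverable; it does not certify accuracy on real
genome databases, where class separation is set by biology rather
than by `p_signature`.

Benchmark scale used by the test suite: 8 order-level classes
(including the non-giant-virus class), 16 family classes, 100 genomes
per order, a 600-GVOG pool with 400 signature GVOGs, nested CV with
10 outer and 3 inner folds over a compact grid. At this separation
the nested-CV mean accuracy is at ceiling (= 1.0) at both levels, and
models trained with fragment augmentation lose no measurable accuracy
at 50% completeness.

## Numerical conventions and degenerate inputs

* Zero denominators in precision/recall/F1 yield 0 (recorded
  convention, visible in the per-class report).
* Predicted class is the argmax of tree-vote fractions with
  lexicographic tie-break; probability vectors sum to 1 within 1e-9.
* Row-normalized confusion matrices divide by row sums only where the
  class has support.
* A genome with no retained hits still gets a prediction (its GC and
  an all-zero profile are legitimate inputs); confidence flags warn
  when the top probability is below 0.5.
* Sequences consisting solely of ambiguity codes are an error for GC,
  not a silent 0.
* Classes smaller than the fold count trigger fold reduction with a
  warning rather than an error.

## Known limitations

* Impurity-importance SDs are unavailable (backend limitation); only
  means are ranked.
* The RFE elimination schedule runs once on the full data and is then
  scored by CV per size; a fully fold-nested RFE would be slower and
  was not needed for the curves' purpose here.
* The family model only knows the family classes present in training;
  genuinely novel families can only land in an order-level aggregate
  bin or be flagged by low probability.
* AAI is one-way and protein-count-normalized; reciprocal AAI and
  aligned-fraction variants are out of scope.
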