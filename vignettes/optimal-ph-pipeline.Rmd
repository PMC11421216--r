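---
title: "Predicting enzyme optimal pH from sequence: models, splits and evaluation"
author: "phopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enzyme optimal pH from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phopt)
```

# The problem

An enzyme's catalytic activity peaks at a characteristic pH. Databases
record this optimum (sometimes as a point value, sometimes as a range, and
often several times per protein with disagreeing values), and the
prediction task is: given only the amino-acid sequence, estimate the
optimal pH. Two features of the available data shape everything in this
package:

1. **Labels are noisy and redundant.** The same protein is measured
   repeatedly under different conditions; observations must be curated
   into one defensible label per sequence, and irreconcilable proteins
   must be dropped rather than averaged into fiction.
2. **Sequence space is clustered.** Proteins come in homologous families.
   A random train/validation split places close homologs — near-duplicate
   feature vectors with near-identical labels — on both sides, so the
   validation score measures memorization plus lookup, not prediction.
   Evaluation protocols that control this leakage are the core of the
   package.

# Curation

`curateOptimalPh()` pools, per protein, all point observations together
with the midpoints `(lo + hi) / 2` of all range observations, then applies
a dispersion filter: if the pooled values have population standard
deviation greater than 1.0 pH units the protein is discarded, otherwise
the label is the pooled mean. Three choices deserve justification:

* **Population (divide-by-n) standard deviation, strict `>`.** The filter
  is a dispersion test on the complete set of recorded values, not an
  inference about a larger population of measurements; the population
  form is also defined for n = 1, which makes "singletons are always
  kept" a theorem rather than a special case. The threshold is exposed as
  `stdThreshold` for users who prefer the sample form (they can rescale).
* **Midpoints are pooled with point values before the filter.** A range
  is treated as one observation located at its center. Nothing in the
  data says whether a range is better or worse evidence than a point, so
  it gets equal weight.
* **pH bounds [0, 14] are enforced at ingest**, where a violation is a
  recording error; curation itself never produces values outside the
  convex hull of its inputs.

Mean growth pH — the average environmental pH of the organisms a protein
occurs in — is a different quantity with a different aggregation:
`aggregateGrowthPh()` first averages within each organism, then averages
the per-organism means with equal weight, so an organism measured a
hundred times counts once. The same std > 1.0 discard is applied on the
per-organism means (`curateGrowthPh()`).

# Splitting strategies

## Homology split

`pairwiseSimilarity()` scores each pair by an optimal global alignment
with match = 1, mismatch = 0 and no gap penalty — the maximal number of
identical residue pairs any alignment can realize, equal to the longest
common subsequence — normalized by the *shorter* raw sequence length.
Dividing by the shorter sequence is deliberately strict: a perfect
fragment of a long multidomain protein scores 1 and is treated as the
homolog it is. The scorer is implemented in C++ (an n×m dynamic
programme per pair); users with MSA-derived or other external scores can
substitute any matrix via `readMatrixFile()`.

Distances `D = 1 − S` feed `densityCluster()`, a standard DBSCAN over the
precomputed matrix: points with at least `minSamples` neighbors (self
included) within `eps` are core; clusters are maximal density-connected
sets, grown in id order so results are deterministic; all noise points are
merged into a single *orphan cluster* so every sequence is assigned.
`clustersToSplit()` then shuffles clusters by seed and assigns them whole
to the validation side until it reaches a quarter of the data (the 3:1
convention); the orphan cluster participates as one ordinary — possibly
huge — cluster.

Numerical and semantic choices:

* `eps` is a distance on [0, 1]; useful values in practice are 0.2–0.6
  (identity 80 %–40 %). `minSamples` defaults to 5, the common library
  default; the orphan cluster only exists for `minSamples > 1`.
* The leakage guarantee — every cross-split pair farther than `eps` — is
  strict exactly at `minSamples = 1`, where DBSCAN degenerates to
  connected components of the eps-threshold graph. At larger
  `minSamples`, border/noise handling can place two points within `eps`
  into different clusters; this is inherent to DBSCAN, documented rather
  than patched. The test-suite verifies the `minSamples = 1` equivalence
  against an independent union-find oracle.
* One published description of this construction states the cross-cluster
  distance condition with "≤ ε"; read literally that would maximize
  leakage, so the package implements the standard semantics (different
  clusters are separated *beyond* ε at `minSamples = 1`).
* A cluster whose assignment would leave the training side empty is
  skipped; a single all-covering cluster is an error, not a silent
  degenerate split.

## PFAM hold-out and EC split

`pfamHoldoutSplits()` builds one split per family annotation: all carriers
form the validation set, everything else (including unannotated records)
trains. Annotations covering nobody or everybody are skipped and reported.
`ecSplit()` classifies by the leading integer of the EC code: proteins
with only hydrolase codes (class 3) are partitioned into `nFolds`
near-equal seeded folds, proteins with only non-hydrolase codes form one
training set, and bifunctional proteins carrying both are discarded —
their membership is ambiguous on both sides. Records with no EC
annotation are likewise reported as discarded rather than silently
assigned. Truncated codes ("3.2.1.-", bare "3") parse fine; only the top
class matters here.

## Enrichment

`enrichTraining()` grows the training side of an existing split with new
data. In homology mode a new sequence is admitted only if its distance to
*every* validation sequence exceeds `eps` — enrichment can never
reintroduce the leakage the split removed. Without a guard (`eps = NULL`)
all new sequences join, the right behavior for a random-split protocol.

# The k-mer baseline

Training associates every k-mer occurrence with its sequence's label and
stores per-k-mer mean, min, max and count (`buildKmerTable()`; one pass,
reusable). Prediction averages the table means over the N = L − k + 1
query occurrences. Two deliberate ambiguity resolutions:

* **k defaults to 3.** The vocabulary (20³ = 8000) is small enough to be
  densely populated by a few hundred training sequences yet specific
  enough to separate families; k is a flag, and the table is stored
  sparsely with an open vocabulary, so noncanonical residues simply form
  rare k-mers.
* **Occurrence multiset vs set.** The query side counts occurrences, so
  by symmetry the default table building lets every training occurrence
  contribute one label copy (`multiset = TRUE`); the strict set reading
  is available as a flag. For the common case — a k-mer appearing once
  per sequence — the two agree.
* **`literal` vs `present_only`.** The faithful dot product treats absent
  k-mers as zeros, which drags predictions toward pH 0 — defensible as a
  definition, chemically absurd as an estimate. `literal` remains the
  default for reproduction; `present_only` (denominator = matched
  occurrences only, training-median fallback when nothing matches,
  flagged) is the recommended practical mode, and is what the
  range variant needs for its `lo ≤ hi` guarantee.

# Embeddings and regressors

`onehotEmbed()` averages position-wise one-hot indicators over the fixed
alphabet `ACDEFGHIKLMNPQRSTVWY` — a residue-composition vector, d = 20.
Noncanonical residues contribute a zero row but count in the denominator,
penalizing unknown content proportionally; a 21st unknown-channel variant
is available. Sequences longer than `maxLength = 5000` residues are
truncated to their first 5000 before embedding — the convention for
fixed-budget language-model backends, applied uniformly so all embedders
see the same input. Deep embedders are intentionally *not* reimplemented:
they enter through `customEmbedder()` (any deterministic
sequence → vector function; record the pooling choice in the name) or
`importEmbedder()` for precomputed tables. The package's contribution is
the protocol around the embedding, not the embedding itself.

`fitRegressor()` covers KNN (Euclidean distance, uniform or
inverse-distance weights, exact-match short-circuit, ties broken by
training order), gradient-boosted trees (xgboost, single-threaded and
seeded so runs reproduce bit for bit), and the naive median — the
MAE-optimal constant and therefore the correct "no information"
reference. `gridSearch()` tunes over a user-overridable default grid
(KNN: k ∈ {1, 3, 5, 10, 20} × two weightings; GBT: depth {3, 6} ×
trees {100, 300} × learning rate {0.05, 0.1}) by seeded k-fold
cross-validated MAE — MAE rather than rank correlation because it is the
headline metric of the evaluation protocol; Spearman selection is a flag.
Infeasible grid entries (e.g. k exceeding a fold) are skipped, not fatal.

# Evaluation

`evaluatePredictions()` reports MAE and Spearman rank correlation
(average ranks under ties; `NA` — undefined — for constant predictions,
as produced by the naive model, rather than a fake 0). Because curated
labels crowd around neutral pH, a constant predictor looks deceptively
good; the δ-protocol removes validation points whose *true* label lies
within δ of the filter center and recomputes both metrics for
δ ∈ {0, 0.5, 1.0, 1.5}. Two conventions:

* The vicinity is **open** (remove |y − center| < δ, keep boundary
  points), so δ = 0 is exactly "no filter"; a closed variant is a flag.
* The center is the **training-label median**, passed by the caller, not
  the pooled-data median: the evaluation protocol itself must not read
  test labels.

The filter is applied to the validation side only; training data are
what they are.

# The synthetic generator, and what passing tests mean

`simulateDataset()` emulates the structure the pipeline assumes: families
are point-mutant radiations (substitutions only — no indels, keeping
identity analysis exact) of uniform-random seed sequences; each family
carries a base pH, drawn from [6, 8] for 56 % of families (curated real
label sets concentrate near neutral) and uniformly from [3, 11]
otherwise; each record receives repeated measurements (base + Gaussian
noise, sd 0.3 pH units, clamped to the chemical scale), a fifth emitted
as ±0.2 ranges to exercise midpointing; annotations are synthetic: the
PFAM accession encodes the family, half the families carry hydrolase EC
codes, each family gets a superkingdom. The reference conditions used
throughout the tests and the acceptance script are 20 families × 25
members at 120 residues, mutation rate 0.05 — small enough that the full
all-vs-all alignment, clustering and grid search run in well under a
minute, large enough for stable metrics. The measurement-range fraction
(0.2) and the ±0.2 half-width are generator conventions, not estimates of
any database's composition.

What the generator does **not** emulate is as important: real amino-acid
composition, indels, database-specific EC distributions — and, above all,
any *cross-family* relationship between sequence and optimal pH. Within a
family, members share a base pH and nearly identical composition, so
under a **random split** an embedding regressor recovers labels almost to
the noise floor (KNN MAE ≈ 0.16 vs naive ≈ 1.03 at the reference
conditions), which is precisely the leakage the protocol warns about.
Under a **homology split** at `eps = 0.4`, clusters coincide with the
planted families, validation families are entirely unseen, and their base
pH is — by construction — independent of everything in training: no
predictor can beat the naive median in expectation, and measured KNN and
naive MAEs agree to within ~0.01. Passing random-split recovery plus
homology-split collapse is therefore the *correct* joint outcome for this
generator: the first shows the models and tuning work, the second shows
the split actually removes the signal it claims to remove. A
homology-split recovery bound (e.g. "MAE below twice the label noise")
cannot be met by any method on data of this design — on real proteins it
is attainable only to the extent that composition and pH are genuinely
correlated across families, which is exactly what such a benchmark would
be measuring.

# Reproducibility and degenerate inputs

Every stochastic stage (splitting, fold assignment, packing, simulation,
tree fitting) takes an explicit seed, restores the RNG state afterwards,
and one pipeline-level seed drives them all in `runPipeline()`; artifact
files are written in sorted id order, so equal runs are byte-identical.
Degenerate inputs fail loudly and early: empty sequences, duplicate ids,
pH values off the chemical scale, lo > hi ranges, measured ids missing
from the FASTA, unparseable EC codes (named by id), embedders returning
the wrong dimension, and validation/train collisions during enrichment
are all errors listing the offending records. Predictions never silently
extrapolate: k-mer queries with no table hit fall back to the training
median and are flagged as such.

# Known limitations

* The identity scorer is alignment-based but gap-cost-free; it is a
  similarity for *leakage control*, not a substitute for evolutionary
  distance. For large n its O(n² · L²) cost dominates; precomputed
  matrices are the intended escape hatch.
* DBSCAN's leakage guarantee is strict only at `minSamples = 1`; larger
  values trade a strict guarantee for noise robustness.
* The EC split keys on the top-level class only; finer-grained
  reaction-specific protocols would need their own fold logic.
* `runPipeline()` drives the two single-split strategies end to end;
  PFAM and EC protocols are exposed as functions (and CLI subcommands)
  because their outputs are families of splits/folds, not one split.
* No uncertainty quantification is attached to predictions; the δ-table
  and the naive baseline are the calibration instruments provided.
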