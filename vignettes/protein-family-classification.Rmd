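---
title: "Classifying protein families from sequence-derived physicochemical features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying protein families from sequence-derived physicochemical features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profam)
```

## The problem

Many protein superfamilies — the DEP-domain-containing (DEPDC) proteins are a
good example — are defined by a shared structural domain rather than by
overall sequence similarity, and the question arises whether membership can
be predicted from the primary sequence alone. `profam` implements a complete
binary-classification pipeline for this setting: redundancy reduction of the
input sequence sets, extraction of fixed-length physicochemical feature
vectors, oversampling to counter class imbalance, random-forest
classification under stratified cross-validation, and the standard
confusion-matrix summaries. It also provides the two supporting analyses
such a study typically reports: a neighbor-joining phylogeny of the family
with bootstrap supports, and comparative-Ct qPCR statistics for expression
follow-up of family members.

## Redundancy reduction

Training on a database dump overstates performance when near-identical
sequences land in both training and test splits. `cluster_sequences()`
performs greedy incremental clustering in the style of CD-HIT: records are
sorted longest first and each record joins the first cluster whose
*representative* it matches at or above a fractional identity threshold
(default 0.90), otherwise it founds a new cluster. Identity between two
sequences is defined as the maximum number of identical aligned residue
pairs (a global alignment with match +1, mismatch 0 and free gaps — the
longest common subsequence) divided by the length of the shorter sequence.
Only representatives are compared, so the set of representatives is
pairwise below the threshold.

Two implementation notes. The alignment engine is
`Biostrings::pairwiseAlignment` with a 0/1 substitution matrix, and the
test suite checks it against an independent dynamic-programming LCS oracle.
Second, a composition screen skips alignments that provably cannot reach
the threshold: the number of identical aligned pairs is bounded above by
the per-letter count overlap `sum_a min(n_a, m_a)`, so a pair whose bound
divided by the shorter length is below the threshold can be rejected
without aligning. We deliberately did *not* use a k-mer containment screen:
for an identity defined through a gapped alignment, shared k-mers are not a
valid necessary condition (a sequence interleaved with insertions keeps
identity 1 while sharing no k-mers), so such a screen could change
results. The composition screen cannot.

## Feature vectors: 20D and 188D

The 20D vector is the amino-acid composition (AAC): the frequency of each
canonical residue, in alphabetical order, summing to 1.

The 188D vector appends, for each of eight physicochemical properties, the
classical composition/transition/distribution (CTD) descriptors. Each
property partitions the 20 residues into three classes (for example
hydrophobicity: polar / neutral / hydrophobic). For a sequence of length
`L`:

* **Composition** (3 values): fraction of residues in each class.
* **Transition** (3 values): for each unordered class pair, the number of
  adjacent positions whose residues fall in the two different classes,
  divided by `L - 1`.
* **Distribution** (15 values): for each class, the 1-based positions of
  its first occurrence and of the occurrences at the ceiling of 25%, 50%,
  75% and 100% of that class's count, each divided by `L` (all five are 0
  for an absent class). Values are reported as fractions in `[0, 1]`.

That is 21 features per property, 8 × 21 = 168, plus 20 AAC features = 188.
The eight 3-class partitions (hydrophobicity, normalized van der Waals
volume, polarity, polarizability, charge, secondary structure, solvent
accessibility, surface tension) are shipped as a documented constant,
`ctd_groupings()`, following the classical CTD literature; published
variants differ slightly in the surface-tension partition, so every
CTD function accepts a custom grouping for users who need a different
convention. Quantile indices use `ceiling(q * n)`; for a single-occurrence
class all five distribution features equal the first-occurrence position
over `L`. Transitions of a length-1 sequence are defined as zero rather
than an error; classifier inputs should filter such sequences upstream
(188D extraction itself requires `L >= 2`).

The extractor is verified feature-by-feature against an independently
coded brute-force implementation on random sequences of lengths 2–500.

## Class imbalance: SMOTE

Family-versus-background datasets are typically very imbalanced. `smote()`
implements synthetic minority oversampling with the Weka filter's
percentage semantics, since that is the convention most workbench users
know: `percent = 700` *adds* `7n` synthetic rows to a minority of size `n`
(the minority grows from 100% to 800% of its original size); in general
`floor(percent / 100) * n` rows are produced. Each synthetic row is
`x + u (z - x)` with `x` a minority row, `z` one of its `k = 5` nearest
minority neighbors under the Euclidean metric on raw feature values, and
`u ~ Uniform(0, 1)`. When `n - 1 < k`, all `n - 1` neighbors are used. No
feature scaling is applied by default, matching the filter's behavior on
CTD features, which are already commensurate fractions.

## Classification and evaluation

`train_rf()` delegates tree induction to the `randomForest` package
(100 trees, `mtry = floor(sqrt(d))` by default); the model's score is the
positive-class vote fraction. A degenerate design in which *every* feature
is constant admits no split; `train_rf()` then returns a prior model whose
score is the training positive-class frequency, which keeps the no-signal
behavior well defined.

`crossvalidate()` runs stratified k-fold cross-validation (default 10) and
pools out-of-fold predictions into a single confusion matrix. Two
protocols are offered because they answer different questions:

* **within-fold** (default): SMOTE is applied to the training split of
  each fold only. Held-out instances never influence synthetic points, so
  the estimate is honest.
* **paper-mode**: the whole dataset is oversampled first and folds are
  drawn from the augmented data, replicating the common workbench
  workflow of filtering before cross-validating. Synthetic points derived
  from test instances can then appear in training, which biases the
  estimate upward; the mode exists to reproduce results obtained under
  that protocol and is documented as optimistic.

Metrics follow the four standard formulas (Sn = TP/(TP+FN),
Sp = TN/(TN+FP), Acc = (TP+TN)/N, and Matthews correlation with the
0-denominator convention MCC = 0), reported both as fractions and as
one-decimal percentages as the field's tables print them. AUC is computed
by the rank-sum identity with midranks, which handles ties exactly and is
tested to equal both all-pairs enumeration and tie-aware trapezoidal
integration.

```{r}
cm <- confusion_matrix(tp = 11027, fn = 523, fp = 301, tn = 10062)
metrics_summary(cm)$percent
```

(These counts are a published random-forest cross-validation of
DEP-domain-containing versus control proteins on 188D features; note that
the analogous 20D table yields Acc = 93.3% by the formula even though the
accompanying text rounds it to 93.2% — the package always reports the
computed value.)

## Phylogeny: p-distance, neighbor joining, bootstrap

`p_distance()` computes the proportion of differing sites over comparable
columns. The default gap policy is pairwise deletion (sites ungapped in
both sequences), the common default of the desktop tree programs;
complete deletion (drop any column containing a gap) is also provided
since publications frequently do not state which was used. A pair with no
comparable sites is an error.

`nj_tree()` is a from-scratch Saitou–Nei neighbor-joining implementation:
Q-criterion minimization with ties broken by the lowest (i, j) index pair,
rate-corrected branch lengths, and clamping of negative branch lengths to
zero with the deficit moved to the sister edge so the path length through
the join is preserved. On additive matrices it reproduces every pairwise
path length to numerical precision, which the suite verifies on 50 random
additive trees of 4–12 taxa (and cross-checks the topology against
`ape::nj`). `midpoint_root()` places the root at the midpoint of the tree
diameter (delegated to `phangorn::midpoint`, with a deterministic
fallback — rooting on the first tip's edge — when every branch length is
zero and the midpoint is undefined).

`bootstrap_support()` resamples alignment columns with replacement (500
replicates by default), recomputes distance matrix and tree, and scores
each internal edge of the reference tree by the fraction of replicate
trees containing the same leaf bipartition. Replicates in which some pair
loses all comparable sites are dropped and counted rather than failing the
run. Supports survive re-rooting because they are keyed by unrooted
bipartitions (`assign_supports()` re-attaches them to any rooting).

One structural point discovered while validating: the synthetic alignment
generator (below) derives every clade ancestor independently from a single
root sequence. The implied deep topology is therefore a *star* — with four
or more clades the tree contains a true polytomy, and the NJ edge that
arbitrarily resolves it has no signal and no stable bootstrap support, no
matter how divergent the clades are. Support benchmarks in the test suite
therefore use three clades of two leaves: in a six-taxon unrooted tree all
`n - 3 = 3` internal edges are genuine clade splits, and every support is
expected to approach 1 under strong signal.

## qPCR group comparison

`relative_expression()` implements the comparative-Ct method: expression
relative to a same-sample housekeeping reference is `2^-(Ct_target -
Ct_reference)`. `compare_groups()` summarizes each group (case/control) by
the mean and standard error of the relative expression and compares the
groups with the Mann–Whitney U test, starring p < 0.05 (`*`) and p < 0.01
(`**`). Samples are treated as unpaired, matching the test named by
typical study designs even when tissues are patient-paired; a paired
Wilcoxon alternative is deliberately out of scope.

`mann_whitney_u()` computes `U = #{x_i > y_j} + 0.5 #{ties}` and, for
combined sizes up to 16, an *exact* two-sided p-value by full enumeration
of all `choose(m + n, m)` group labelings — valid in the presence of ties,
which the standard exact algorithm refuses. The two-sided p is
`min(1, 2 min(P(U <= u), P(U >= u)))`. Larger samples use the normal
approximation with tie-corrected variance and continuity correction. The
suite checks the exact p against a brute-force enumeration oracle for all
group sizes up to 8 × 8 and against `stats::wilcox.test` on tie-free data.

`primer_gc()` is a small QC helper for primer panels (percent G+C from the
sequence); it intentionally recomputes from sequence rather than trusting
printed table values, which occasionally disagree with their own primers.

## Synthetic data

All tests run without downloads because the `gen_*` generators produce
inputs with the statistical structure each stage assumes; all are pure
functions of their specification and seed.

* `gen_family()` draws i.i.d. sequences from a background residue
  distribution, optionally shifted so that a designated residue subset
  reaches a target total frequency (`bias_strength` is the probability
  mass added), and optionally embeds a fixed motif once per sequence at a
  random position. Two families differing by a compositional shift of
  0.15–0.20 are reliably separable by the 188D features, which is the
  package's end-to-end benchmark (two families of 200 sequences of length
  80–200, dedupe at 0.90, 10-fold within-fold-SMOTE cross-validation:
  accuracy is expected at or above 0.90, and a permuted-label control
  near 0.5). These sizes keep the full benchmark under a few minutes on a
  single core while leaving the conclusions unchanged at larger n.
* `gen_alignment()` mutates clade ancestors from a root sequence at a
  between-clade rate and leaves from ancestors at a within-clade rate;
  per-site substitution to a uniformly random different residue, no
  indels (gapped fixtures for the gap policies are crafted separately in
  the tests). There is no rate heterogeneity or substitution matrix; the
  generator is meant to give controllable p-distance structure, not
  realistic protein evolution.
* `gen_ct_table()` draws control delta-Ct from `Normal(base, sd)` and
  shifts cases by a per-gene effect (negative = up-regulated), with the
  reference Ct fixed at 20 cycles. With an effect of −3 cycles
  (about 8-fold), noise of 0.5 cycles and 8 samples per group, the
  Mann–Whitney test detects the shift in well over 90% of simulations.

What the generators do *not* emulate bounds what passing tests show:
real protein families share homology (phylogenetic correlation between
sequences, domain architecture, indels), not merely compositional bias,
and real qPCR data have technical replicates and non-normal noise. The
pipeline's measured accuracy on synthetic families demonstrates that the
machinery is correct, not what accuracy to expect on a real family.

## Numerical and design choices

* Sanitization default is `map-common` (B→N, Z→Q, U→C, O→K, J→L, drop
  X/*), the most information-preserving treatment of database ambiguity
  codes; `error` and `drop-residue` policies are available. Sanitization
  is idempotent under every policy.
* FASTA output wraps at 60 columns; record ids are the first
  whitespace-delimited header token and must be unique.
* All stochastic operations (SMOTE, forests, folds, bootstrap,
  generators) take explicit seeds, restore the caller's RNG state, and
  are bitwise reproducible for a fixed seed; per-fold seeds are derived
  from the top-level seed so folds are independent but reproducible.
* NJ ties are broken by the lowest index pair; the bootstrap drops (and
  reports) degenerate replicates; the midpoint of a zero-length tree is
  resolved deterministically.
* Newick output quotes labels containing metacharacters and writes
  bootstrap supports as internal node labels.

## Limitations

* The identity screen and greedy clustering reproduce CD-HIT's *contract*,
  not its banded-alignment heuristics; on very large sets it is slower
  than the original tool.
* `paper-mode` cross-validation is intentionally optimistic; use it only
  to reproduce results obtained under that protocol.
* Exact Mann–Whitney enumeration is limited to combined sizes of 16; the
  approximation beyond that is accurate to a few hundredths of a p-value
  at moderate sizes but should not be trusted for extreme tails at tiny n.
* Motif discovery, multiple-sequence alignment construction and
  model-based distances (JTT, Poisson-corrected) are out of scope; the
  phylogeny module consumes pre-aligned input.
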