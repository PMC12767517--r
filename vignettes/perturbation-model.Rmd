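---
title: "Interaction-specific perturbation prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-specific perturbation prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(edgotyper)
```

This vignette documents the scientific model implemented by `edgotyper`, the
choices made where the design was genuinely open, and what the synthetic
test framework does and does not establish.

## The problem and the unit of prediction

A missense variant can abolish some of a protein's interactions while
sparing others (an *edgetic* effect). The unit of prediction is therefore
the triplet (i, v, p) — interactor protein, variant, partner protein — and
the output is Pr(loss of the specific interaction i–p under v), not a
per-variant pathogenicity score. Aggregating predictions across a variant's
partners yields its *edgotype*: quasi-wild-type (no interaction predicted
lost), quasi-null (all lost), or edgetic (mixed).

## From structure to graph

The two-chain complex of (i, p) is reduced to a residue contact graph. Two
residues are in contact when **any** heavy-atom pair is within 4.5 Å; the
boundary is inclusive (a distance of exactly 4.5 Å is a contact), and both
intra- and inter-chain contacts are kept. Decisions taken where a structure
file leaves room:

* *Heavy atom* means any non-hydrogen, non-deuterium atom, side chains
  included. Waters and hetero ligands (HETATM records) are outside the
  residue-graph model and are dropped.
* Alternate locations are resolved to the highest-occupancy conformer, ties
  broken by altloc identifier order.
* Residues are renumbered sequentially from 1 within each chain, ignoring
  author numbering gaps, so variant positions index the FASTA sequence.
* Non-standard residues map to `X` and are embedded like any residue.
* There are no self-edges; a node's relation to itself enters through
  self-attention in the model.

Contact computation compares squared distances to the squared threshold, so
no precision is lost to a square root at the boundary.

## Features

Per-residue embeddings come from a pluggable embedder. In production this
is a protein language model such as ProtT5 (dimension 1024), consumed from
a precomputed keyed cache; the packaged synthetic embedder (default
dimension 32) composes a per-amino-acid base vector with a smaller
local-context term hashed from the surrounding k-mer, which preserves the
two properties the pipeline relies on: determinism (identical sequences give
bit-identical matrices) and locality (a substitution perturbs only rows
within the context window).

Node features deliberately combine the **mutant** interactor embedding with
the **wild-type** partner embedding — recomputing a complex structure per
variant would be prohibitive, and predicted structures are largely
insensitive to single substitutions, so variant context is carried by the
embeddings instead. For variants on the partner chain the roles are flipped
upstream (`flip_roles()`, or `predict --flip-roles` in the CLI); the model
contract itself is single-directional.

The mutation encoding is the difference between mutant and wild-type
residue embeddings at the variant site, z-score normalized across variants.
Two under-specified points are fixed as follows:

* the normalizer is fitted on **training-fold variants only** and applied
  frozen to test variants — fitting on all data would leak test statistics
  into training;
* the population standard deviation (divide by n) is used, and
  zero-variance dimensions map to 0.

## Architecture and training

The classifier has three components:

* **GAT stack** — 2 graph-attention layers (4 heads, hidden dimension 128
  by default; 64 in the reduced test configuration), ELU activations,
  dropout 0.2 during training, self-loops added for attention. The whole
  complex graph is propagated; reading out the mutation-site node after 2
  layers gives a 2-hop receptive field, which is what focuses the model on
  local structural context at the variant.
* **Mutation processor** — a 2-layer ReLU feed-forward network from the
  normalized encoding to the hidden dimension.
* **Head** — a 2-layer feed-forward network on the concatenation of the
  mutation-site representation and the processed encoding, ending in a
  single logistic output, so predictions lie strictly in (0, 1).

Training is two-stage: pretraining on stability labels derived from ΔΔG
(|ΔΔG| < 0.5 kcal/mol preserving, ≥ 1.5 disrupting, the band in between
excluded) over monomer graphs built with the same contact rule, then full
fine-tuning (no frozen layers) on interaction-perturbation labels. The
stability-disrupting and interaction-lost polarities are aligned, so the
binary head is shared between stages. Both stages use class-weighted binary
cross-entropy with inverse-frequency weights w_c = n/(2·n_c). Optimization
is Adam (learning rate 1e-3 for pretraining; 1e-4 is the conventional
fine-tuning default, configurable) with early stopping on a 10% validation
split (patience 10) when the training set is large enough to afford one.
The forward and backward passes are implemented natively as dense masked
matrix operations — graphs here are small (tens to hundreds of residues), so
a sparse formulation would add complexity without measurable benefit — and
all randomness (initialization, shuffling, dropout) flows from one seed, so
identical configurations reproduce identical losses bit for bit.

## Leakage-aware evaluation

Paired-protein inputs leak information in two distinct ways, and the
evaluation treats them separately:

1. **Sequence similarity** — variant-partner pairs are clustered on the
   concatenated wild-type sequences at a 50% identity threshold, and group
   k-fold cross-validation assigns whole clusters to folds. The built-in
   clustering replicates the greedy longest-first scheme of CD-HIT
   (identity = identical ungapped positions / shorter length); a parser for
   external `.clstr` files is provided for runs where the real tool is
   preferred.
2. **Shared proteins** — test pairs are binned by identifier into classes
   C1/C2/C3 (both / one / neither protein present among that fold's training
   proteins). Binning is per fold, because the relevant question is what
   the model that scores a pair has seen. Class bins with fewer than 30
   points are recorded but excluded from aggregates.

Per-class AUCs (rank-based, ties counting one half) are aggregated over
folds and iterations weighted by test-bin size. Mean ROC curves average the
per-fold step functions vertically on a fixed 101-point false-positive-rate
grid. Benchmark (blind-test) evaluation scores an ensemble of the k fold
models by mean probability, after excluding benchmark variants whose
(interactor, mutation) key occurs in training, and bins against the full
training protein set.

## Edgotypes and enrichment

Partner-wise probabilities are thresholded at 0.5; a probability exactly at
the threshold counts as perturbed (the threshold's direction is otherwise
arbitrary, and this choice is asserted in tests). Variants with fewer than
three tested partners are dropped when the interaction catalogue lists three
or more partners; variants with genuinely small catalogues are processed
normally. A multiplicative quasi-null probability across partners is
deliberately **not** offered: partner-wise outputs are correlated and not
calibrated as independent probabilities, so the product has no sound
interpretation.

Group-level enrichment of an edgotype against a population baseline uses
E = (f_obs − f_base)/(f_obs + f_base), bounded in [−1, 1] with the extremes
attained exactly when one rate is zero. Bootstrap choices, where the
procedure is open:

* resampling is over **variants** (profiles), not variant-partner pairs, in
  the group and the baseline independently — the variant is the edgotype
  unit, and partner-wise probabilities within a variant are dependent;
* the partner-controlled mode samples exactly three partners per variant
  (without replacement; variants with fewer use all of them) in **both**
  groups — asymmetric treatment would bias the comparison. Because the
  edgotype of a subsample depends only on how many sampled partners are
  perturbed, the per-variant subsample distribution is hypergeometric and is
  computed in closed form rather than by inner-loop simulation;
* the point estimate is computed on the full data, not the bootstrap mean;
* iterations where both rates are zero leave E undefined; they are
  discarded and counted, never coerced to 0;
* the 68% confidence interval is the (16th, 84th) percentile pair;
* significance is sign consistency of the bootstrap distribution with the
  point estimate, compared against 1 − α/n_tests (Bonferroni, default
  α = 0.05, n_tests = 64 or twice the number of strata in a report) and
  1 − α (uncorrected).

## The synthetic test framework

The generators exist so that training, evaluation and enrichment are
testable with no external downloads, with planted ground truth:

* **Geometry** — two chains along parallel axes with central interface
  patches whose paired pseudo-atoms sit ~4.3 Å apart while every non-patch
  residue stays > 6 Å from the other chain, so the planted interface is
  unambiguous at the 4.5 Å rule and `interface_nodes()` recovers exactly
  the patch.
* **Composition** — interface patches and buried cores draw from a
  hydrophobic alphabet disjoint from the rest of the chain, emulating the
  compositional bias of real interfaces; this is what makes the planted
  rules learnable from embeddings plus graph structure alone.
* **Labels** — interaction labels follow an interface-disrupts rule with
  site-level inversions at rate ε (a site behaves consistently across
  partners, as real site effects do); stability ΔΔG values are drawn inside
  the preserving/disrupting bands according to a buried-disrupts rule.
* **Population structure** — proteins are cloned within sequence families
  (≤ 10% within-class substitutions) and recur across pairs with variable
  chain lengths, so sequence clustering, group CV and the C1/C2/C3 classes
  are all non-trivially exercised.
* **Edgotype scenarios** — per-stratum quasi-null/edgetic rates are planted
  and partner probabilities drawn consistently with the drawn class.

What passing tests on this framework shows: the implementation recovers
planted signal at the stated noise level, respects every leakage rule, and
is deterministic. What it does not show: performance on real variants — the
synthetic sequences have no evolutionary structure, the geometry no
physics, and the labels no assay noise model beyond ε, so measured AUCs
here do not transfer to real corpora.

## Problem sizes and numerical choices

The test suite runs at deliberately modest scale, chosen to exercise every
code path at study-like conditions: the planted-signal recovery uses 450
triplets (45 complexes × 10 variants, ε = 0.05) with the reduced model
(D = 32, hidden 64) and a 300-variant stability pretraining set; the
leakage audit runs 3 iterations of 10-fold group CV over 200 triplets; the
bootstrap recovery uses 200 variants per group and 10,000 iterations
(production default 100,000). Other numerics: Glorot-uniform
initialization; leaky-ReLU slope 0.2 inside attention; softmax computed
with row-max subtraction; degenerate inputs (empty chains, single-class
labels, empty profiles, both-zero rates) raise typed errors rather than
returning sentinel values.

## Known limitations

* The GAT is trained sample-by-sample on CPU; it is sized for desk-scale
  experiments and thousands of triplets, not proteome-wide sweeps.
* Gain of interaction is out of scope; the model only scores loss.
* Structure quality filtering (e.g. by predicted-confidence metrics) is the
  caller's responsibility; the parser accepts any readable complex.
* The built-in clustering is an approximation of CD-HIT (no k-mer
  prefilter); for large corpora the external tool's `.clstr` output can be
  supplied instead.
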