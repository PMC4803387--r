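---
title: "Generating protein–ligand binding-site predictors with plbpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating protein–ligand binding-site predictors with plbpred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`plbpred` builds sequence-based predictors of ligand-binding residues. Given
protein–ligand complex structures, it derives a labeled residue dataset,
encodes each residue as a sliding-window profile feature vector, and trains a
binary classifier (SVM, neural network or random forest) whose
hyperparameters are tuned against cross-validated AUC by a genetic algorithm
or grid search. Every stage is a plain R function, so the whole pipeline runs
offline and deterministically.

### Binding residues from structure

A residue is *binding* when at least one of its atoms lies within a cutoff
distance (default **5 Å**, accepted range 3.5–6 Å) of any atom of a ligand
instance. Ligand instances are the non-water `HETATM` groups of a PDB file,
keyed by chemical-component code, chain and residue number. Neighbour search
uses an octree (leaf capacity 8, maximum depth 12 — values chosen for
near-linear build time at protein scale; the result is defined to equal a
brute-force all-pairs scan and is tested against one). Ligands covalently
attached to the polymer or to another ligand — as recorded by `CONECT`/`LINK`
records, never inferred from distances — are excluded before extraction.

Choices the input format forces us to make: only the first model of a
multi-model file is read; only the first alternate location per atom is kept;
waters are discarded; selenomethionine (`MSE`) is folded into the polymer.
Hydrogens, when present, participate in distance tests like any other atom.
A user-editable buffer list (`default_buffer_ccds()`: glycerol, ethylene
glycol, sulfate, phosphate, chloride, sodium) marks components that are
crystallization media rather than ligands of interest; this list is a package
choice, not a community standard. Symmetry-related contacts are not
generated: coordinates are used as given.

### The labeled dataset

Sequences are de-redundified by greedy incremental clustering at **90 %
identity over 50 % coverage** (the defaults of the usual clustering tools).
Identity comes from Needleman–Wunsch global alignment (BLOSUM62, gap open 11 /
extend 1), counted over alignment columns after stripping terminal gaps;
coverage is measured against the shorter sequence. Exact alignment replaces
the word heuristics of dedicated clustering tools: at package scale it is
fast enough and it *is* the definition those heuristics approximate.

Positives are the binding residues of the surviving representatives, pooled
over all instances of the target ligand group (a user-supplied list of
component codes). Negatives are residues **5–25 positions** up- or downstream
of each positive, clipped to the sequence, with positives removed — when a
residue is positive for one ligand instance and inside another's negative
band, the positive label wins, which avoids contradictory labels.

### Window features

Each labeled residue becomes a `w × 21` feature vector: the profile rows of
the `w` consecutive positions centred on it, each row carrying 20
position-specific scores plus one **terminal spacer** flag. A slot outside
`[1, L]` contributes 20 zeros and spacer 1; every in-sequence slot has
spacer 0. The per-slot spacer interpretation is the only one consistent with
the `w × 21` dimension (20 amino-acid channels + 1 spacer per slot).

Profiles come from either of two interchangeable sources:

* a PSI-BLAST ASCII PSSM file (the log-odds block; whether published
  predictors used the log-odds or frequency block is generally unstated — we
  use log-odds and expose the choice), or
* an internal profile computed from a user-supplied multiple sequence
  alignment: `score(a) = log2((count(a) + pc·bg) / ((N + pc)·bg))` with a
  uniform background `bg = 1/20`, `N` the residues observed at the column and
  pseudocount mass `pc` (default 1).

The second route exists so that the whole system runs without a sequence
database; the two share the same profile contract. Scores are divided by
**10** before training (log-odds columns are small integers; RBF kernels want
bounded ranges). The divisor is configurable and recorded on the dataset.

### Learners

All three classifiers sit behind one `train()`/`score()` contract and are
deterministic given a seed:

* **SVM** — soft-margin RBF kernel, `K(x1, x2) = exp(−‖x1−x2‖²/(2σ²))`,
  fitted by a deterministic SMO solver. The kernel's published typography is
  ambiguous about the factor 2; both conventions appear in the literature and
  differ only by a σ rescaling, so the alternative `exp(−d²/σ²)` is available
  as `kernel_variant = "plain"`. Scores are signed decision values.
* **NN** — one hidden layer of sigmoidal units, single sigmoid output,
  squared-error loss, full-batch gradient descent; at most 500 epochs or a
  loss improvement below 1e−6. Only the node count and learning rate are
  published operating parameters; the loss, batch regime and stopping rule
  are package decisions. Scores are sigmoid outputs in (0, 1).
* **RF** — CART trees grown to purity (depth-capped at 30) on bootstrap
  samples, `mtry` features tried per split; "tries per tree" is interpreted
  as the per-split feature sample. Scores are positive-vote fractions.

Class imbalance from the band rule (up to 50 negatives per positive) is left
as-is by default, matching the silence of the published setup.

Defaults mirror the published grid-search operating point: `w = 9`, SVM
`C = 1, σ = 0.1`, NN `25` nodes at learning rate `0.1`, RF `1501` trees with
`20` tries. Note the σ default presumes `/10`-scaled profile features; on
unit-variance synthetic clouds a width of the order of the inter-point
distance (σ ≈ √(2d)) is appropriate, which is what the test suite uses.

### Hyperparameter search

`fitness()` decodes a genotype into hyperparameters (including `w`, re-encoding
the corpus at that window), runs seeded stratified k-fold cross-validation
(default 5-fold) and returns the mean held-out AUC with its standard error
across folds. Fold assignment depends only on the labels, fold count and
seed, so all genotypes in a run see identical folds and fitness differences
reflect parameters, not fold luck.

The GA is generational with tournament selection (size 2), single-point
crossover at rate 0.8, per-gene point mutation at rate 0.05 (uniform redraw
within bounds) and elitism of one — tournament size, elitism and the mutation
distribution are unpublished details fixed here; elitism is what makes the
best-so-far trace monotone. The published operating configuration is 100
generations of 20 individuals; the test suite runs a scaled-down 10 × 10
version for time. Default gene bounds (`C ∈ [0.1, 30]`, `σ ∈ [0.05, 5]`,
nodes `∈ [5, 50]`, learning rate `∈ [0.01, 5]`, trees `∈ [100, 2500]`,
`mtry ∈ [1, 40]`, `w ∈ {3, …, 21}`) are envelopes of published operating
values and are configurable.

A note on GA strength at desk scale: with the published operating constants
(mutation 0.05) and a halved population of 10, the GA loses diversity within
a couple of generations and its search is statistically indistinguishable
from uniform random sampling of the same number of distinct genotypes. The
test suite's GA-versus-random comparison therefore runs the GA at mutation
0.15 — the standard compensation for a smaller population — while the
package defaults keep the published constants for the full-size
configuration.

Grid search evaluates the full Cartesian product through the same fitness
function. Both searches share an evaluation cache keyed by a canonical
serialization of the decoded parameters (reals rounded to 4 decimals, fixed
field order): a repeated genotype is a lookup, never a retraining. The cache
serializes to a single TSV file; an embedded SQL store would add a dependency
for no behavioural difference.

### Evaluation

`cross_validate()` reports per-fold and pooled sensitivity, specificity,
MCC and AUC. The ROC sweeps all distinct thresholds, counts ties one half,
and integrates by trapezoid — equal to the Mann–Whitney statistic, which the
tests verify by exhaustive pair counting. The pooled (concatenated held-out
scores) ROC is the headline number because a single AUC per predictor is the
natural summary; per-fold values are also reported. The operating threshold
for sensitivity/specificity/MCC is fixed by score type (0 for SVM decision
values, 0.5 for probabilities/vote fractions) rather than tuned — published
sensitivity/specificity pairs do not state a threshold-selection rule, and
inventing one would fabricate method detail. MCC is defined as 0 when a
denominator factor vanishes. `holdout_split()` provides the stratified 15 %
test split used in published comparisons.

## What the synthetic generators emulate

* `gen_complex()` — a two-bead (Cα+Cβ) polymer on a jittered linear path with
  6 Å spacing, plus a ligand with one atom per planted binding residue at
  `cutoff − margin`, all other residues provably beyond `cutoff + margin`.
  It exercises fixed-column parsing, octree search, the distance rule and
  covalent exclusion — not protein geometry: there are no rotamers, no
  clashes, no real side chains.
* `gen_sequence_families()` — families mutated from independent random
  ancestors with an exact per-member substitution count, so intra-family
  identity is bounded below by construction and inter-family identity is
  background. Real homologs have indels and domain structure; these do not.
* `gen_labeled_features()` — two Gaussian classes along a random direction in
  window space with the interior-window spacer pattern. It calibrates
  learner sanity (a 4σ separation must be easy; shuffled labels must be
  chance), not biological signal structure.
* `gen_offset_corpus()` — the optimizer's tunable world: the class signal
  lives only in profile rows at offset ±3 from the labeled position, so
  windows narrower than 7 see pure noise; binding sequences carry the signal
  at +δ or −δ alternately while non-binding ones carry none, so a
  near-linear (huge-σ) kernel fails and a tiny σ overfits, giving the kernel
  width a genuine interior optimum; row noise (δ = 2 against unit noise,
  80 sequences) keeps the attainable cross-validated AUC strictly below 1 so
  continuous genes always have room to improve on the initial population.
  These constants were chosen by inspecting the fitness surface — ceiling
  inside (0.95, 1), chance at narrow windows — before the acceptance run,
  and are not revisited.

A green test on these worlds establishes that the machinery implements its
contracts exactly (geometry, set rules, encoding arithmetic, metric
definitions, optimizer bookkeeping); it does not establish predictive
accuracy on real proteins, which depends on real profiles and real binding
geometry that no desk-scale fixture reproduces.

## Numerical and degenerate-input choices

* Octree queries and the brute-force scan must agree exactly; distances are
  compared as squared Euclidean against a squared cutoff, no epsilon.
* A residue index is 1-based by order of appearance per chain, with the
  author numbering (+ insertion code) retained alongside — windowing needs
  dense indices.
* `parse_pdb` on a water-only file returns an empty structure (zero ligands)
  rather than an error; a file with no atom records at all is an error.
* Leave-one-out cross-validation is supported (`folds = n`); per-fold AUC is
  undefined there and reported as `NA`, while pooled metrics remain exact.
* Grid-search ties break toward smaller `w`, then lexicographic parameter
  order, so results are order-independent.
* The GA preserves its own RNG stream across fitness evaluations (which
  reseed internally for reproducible folds), keeping whole runs bit-identical
  under one seed.

## Known limitations

* No mmCIF input, no symmetry expansion, no NMR multi-model handling beyond
  model 1.
* No PSI-BLAST execution: profiles are parsed from files or computed from a
  supplied alignment.
* No residue-conservation or physico-chemical feature channels; no
  probability calibration; no multi-layer networks.
* Published headline numbers for real ligand classes are not reproducible
  here by design: they require full structure-database snapshots and
  large-database profiles.
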