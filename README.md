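# plbpred — automatic generation of protein–ligand binding-site predictors

`plbpred` builds sequence-based predictors of ligand-binding residues, for
structural bioinformaticians who want a binding-site classifier for an
arbitrary ligand without hand-assembling the training machinery each time.
It implements the full generation pipeline:

1. **Structure mining** — parse protein–ligand complexes (PDB format), find
   binding residues (any residue atom within *n* Å of any ligand atom,
   default *n* = 5, via an octree index), and exclude covalently attached
   ligands using `CONECT`/`LINK` records.
2. **Dataset construction** — remove sequence redundancy by greedy clustering
   at 90 % identity / 50 % coverage (Needleman–Wunsch, BLOSUM62); negatives
   are residues 5–25 positions from each binding residue.
3. **Feature encoding** — each residue becomes a *w* × 21 vector: the
   position-specific scoring matrix (PSSM) rows of the *w* residues centred
   on it, 20 scores plus a terminal-spacer flag per slot. Profiles are parsed
   from PSI-BLAST ASCII PSSM files or computed from a multiple alignment.
4. **Learning** — RBF-kernel SVM (`K(x₁,x₂) = exp(−‖x₁−x₂‖²/(2σ²))`, SMO
   solver in C++), a single-hidden-layer neural network, and a random forest,
   behind one `train()`/`score()` contract.
5. **Tuning** — genetic algorithm (tournament selection, single-point
   crossover 0.8, point mutation 0.05, elitism 1) or exhaustive grid search,
   optimizing mean 5-fold cross-validated AUC, with a persistent evaluation
   cache so no genotype is ever trained twice.
6. **Evaluation** — stratified k-fold cross-validation reporting ROC/AUC,
   MCC, sensitivity and specificity, per fold and pooled.

Deterministic fixture generators (`gen_complex`, `gen_sequence_families`,
`gen_pssm_text`, `gen_labeled_features`, `gen_offset_corpus`) emulate every
input, so the whole pipeline runs offline.

## Worked example

```r
library(plbpred)

# a toy complex with binding residues planted at positions 3 and 7
fx <- gen_complex(seed = 7, n_residues = 12, binding_positions = c(3, 7))
s <- parse_pdb(fx$text)
s
#> pl_structure: 26 atoms, 1 chain(s), 1 ligand instance(s), 0 covalent link(s)

extract_binding_residues(s, lig_id = 1, cutoff_A = 5)$residues
#>   chain res_index resseq icode min_distance_A
#> 1     A         3      3                  4.5
#> 2     A         7      7                  4.5
```

The two planted residues are recovered with their planted 4.5 Å minimum
distance; every other residue is provably beyond 5.5 Å.

```r
# train/evaluate an SVM on a separable synthetic feature cloud (w = 9)
fl <- gen_labeled_features(seed = 7, n_pos = 100, n_neg = 100, w = 9,
                           separation_sigma = 4)
cross_validate(fl$dataset, hyperparams("svm", C = 1, sigma = 10, w = 9),
               folds = 5, seed = 7)
#> pl_report: svm, 5-fold CV | AUC 0.989  Sens 91.0%  Spec 95.0%  MCC 0.861
```

Pooled 5-fold CV AUC 0.989 on a 4σ-separated two-class cloud: the held-out
ranking is almost perfect; sensitivity/specificity are read at the SVM's
natural threshold 0.

```r
# GA hyperparameter search on a corpus whose separability is gated by w
oc <- gen_offset_corpus(seed = 42)   # signal only at offsets +/-3
space <- param_space("svm", include_w = TRUE, bounds = list(sigma = c(0.5, 15)))
res <- run_ga(oc$corpus, "svm", seed = 42, generations = 10, pop = 10,
              folds = 5, space = space)
res$trace[c(1, 6, 11), c("generation", "gene_sigma", "gene_w", "mean_auc")]
#>    generation gene_sigma gene_w mean_auc
#> 1           0   4.203718     19 0.934375
#> 6           5   4.203718     13 0.962500
#> 11         10   4.203718     13 0.962500
res$best$fitness
#> [1] 0.9625
```

The best-so-far trace is non-decreasing (elitism) and the GA improves on the
initial random population, 0.934 → 0.963 mean CV AUC, by shrinking the
window toward the informative region.

## Layout

```
R/                  structure_extract, dataset_build, profile_features,
                    learners, hyperopt, evaluate, fixtures
src/                SMO solver and CART forest (Rcpp)
inst/cli/plbpred.R  command-line front-end (extract / dataset / featurize /
                    fixtures)
vignettes/          methods vignette: model, assumptions, parameter choices
tests/testthat/     unit + property + acceptance suites
```
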