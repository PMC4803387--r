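# Independent oracles kept deliberately naive: brute-force scans, exhaustive
# enumeration and pair counting, never sharing code with the implementation.

# all-pairs distance scan: set of chain-local residue indices with any atom
# within cutoff of any atom of the ligand instance
brute_force_binding <- function(structure, lig_id, cutoff) {
  atoms <- structure$atoms
  la <- atoms[!is.na(atoms$lig_id) & atoms$lig_id == lig_id, , drop = FALSE]
  pa <- atoms[atoms$kind == "polymer", , drop = FALSE]
  if (!nrow(la) || !nrow(pa)) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(nrow(pa))) {
    d2 <- (la$x - pa$x[i])^2 + (la$y - pa$y[i])^2 + (la$z - pa$z[i])^2
    if (any(d2 <= cutoff^2)) hits <- c(hits, pa$res_index[i])
  }
  sort(unique(hits))
}

# brute-force radius query over a coordinate matrix
brute_force_range <- function(coords, point, r) {
  d2 <- (coords[, 1] - point[1])^2 + (coords[, 2] - point[2])^2 +
    (coords[, 3] - point[3])^2
  sort(which(d2 <= r^2))
}

# offset-enumeration oracle for the negative band rule
neg_band_oracle <- function(positives, seq_len, mn = 5, mx = 25) {
  out <- integer(0)
  for (p in positives) for (d in mn:mx) out <- c(out, p + d, p - d)
  sort(setdiff(unique(out[out >= 1 & out <= seq_len]), positives))
}

# Mann-Whitney pair counting with ties worth one half
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# a small two-class dataset all learners separate easily
separable_fixture <- function(seed = 10, n_each = 100, w = 9, sep = 4) {
  gen_labeled_features(seed, n_pos = n_each, n_neg = n_each, w = w,
                       separation_sigma = sep)$dataset
}

# fixture-appropriate hyperparameters per algorithm (the unit-variance cloud
# needs a kernel width of the order of the inter-point distance, sqrt(2d))
fixture_params <- function(alg, w = 9) {
  switch(alg,
    svm = hyperparams("svm", C = 1, sigma = 10, w = w),
    nn = hyperparams("nn", hidden_nodes = 25, learning_rate = 0.1, w = w),
    rf = hyperparams("rf", n_trees = 300, mtry = 20, w = w)
  )
}
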