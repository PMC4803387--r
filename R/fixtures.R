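# Deterministic fixture generators: every input the pipeline consumes can be
# produced offline, with a manifest of the planted ground truth.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")

.pdb_atom_line <- function(record, serial, name, resname, chain, resseq,
                           x, y, z, element) {
  # strict fixed columns: name 13-16, altLoc 17, resName 18-20, chain 22,
  # resSeq 23-26, iCode 27, coords 31-54, element 77-78
  sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, chain, resseq, x, y, z, 1.0, 0.0,
          element)
}

#' Generate a toy protein-ligand complex in PDB format
#'
#' Emits a two-bead (CA + CB) polymer laid out along a lattice-like path with
#' 6 A residue spacing, plus one multi-atom ligand placed so that exactly the
#' planted positions have an atom within `cutoff - cutoff_margin` A of a
#' ligand atom while every other residue is farther than
#' `cutoff + cutoff_margin` A. Optionally plants a covalent ligand-polymer
#' bond as a CONECT record.
#'
#' @param seed Integer seed (drives the small deterministic path jitter).
#' @param n_residues Polymer length.
#' @param binding_positions Integer positions (1-based) planted as binding;
#'   may be empty, in which case the ligand is placed 50 A away.
#' @param cutoff_margin Distance margin in angstroms (> 0), default 0.5.
#' @param cutoff Nominal extraction cutoff the margins are built around.
#' @param covalent If `TRUE`, adds a CONECT bond between the first ligand
#'   atom and the CB of the first planted (or first) residue.
#' @param ccd Ligand component code written to the HETATM records.
#' @return List with `text` (character vector of PDB lines) and `manifest`
#'   (seed, planted positions, per-position planted distance, cutoff,
#'   margin, covalent flag).
#' @export
gen_complex <- function(seed, n_residues = 12, binding_positions = integer(0),
                        cutoff_margin = 0.5, cutoff = 5, covalent = FALSE,
                        ccd = "LIG") {
  stopifnot(cutoff_margin > 0, n_residues >= 1,
            all(binding_positions >= 1), all(binding_positions <= n_residues))
  binding_positions <- sort(unique(as.integer(binding_positions)))
  set.seed(as.integer(seed))
  zjit <- stats::runif(n_residues, -0.1, 0.1)
  spacing <- 6
  lines <- character(0)
  serial <- 0L
  cb_serial <- integer(n_residues)
  cb_xyz <- matrix(0, n_residues, 3)
  for (i in seq_len(n_residues)) {
    xa <- spacing * (i - 1)
    serial <- serial + 1L
    lines <- c(lines, .pdb_atom_line("ATOM", serial, "CA", "GLY", "A", i,
                                     xa, 0, zjit[i], "C"))
    serial <- serial + 1L
    cb_serial[i] <- serial
    cb_xyz[i, ] <- c(xa, 1.5, zjit[i])
    lines <- c(lines, .pdb_atom_line("ATOM", serial, "CB", "GLY", "A", i,
                                     xa, 1.5, zjit[i], "C"))
  }
  lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", serial + 1L, "GLY",
                            "A", n_residues))

  lig_serials <- integer(0)
  planted_d <- cutoff - cutoff_margin
  if (length(binding_positions)) {
    for (k in seq_along(binding_positions)) {
      p <- binding_positions[k]
      serial <- serial + 1L
      lig_serials <- c(lig_serials, serial)
      lines <- c(lines, .pdb_atom_line(
        "HETATM", serial, sprintf("X%d", k), ccd, "A", 900L,
        cb_xyz[p, 1], cb_xyz[p, 2] + planted_d, cb_xyz[p, 3], "C"))
    }
  } else {
    serial <- serial + 1L
    lig_serials <- serial
    lines <- c(lines, .pdb_atom_line("HETATM", serial, "X1", ccd, "A", 900L,
                                     0, 50 + cutoff, 0, "C"))
  }
  if (covalent) {
    target <- if (length(binding_positions)) binding_positions[1] else 1L
    lines <- c(lines, sprintf("CONECT%5d%5d", lig_serials[1],
                              cb_serial[target]))
  }
  lines <- c(lines, "END")
  list(
    text = lines,
    manifest = list(seed = seed, n_residues = n_residues,
                    planted = binding_positions,
                    planted_distance_A = planted_d, cutoff = cutoff,
                    cutoff_margin = cutoff_margin, covalent = covalent,
                    ccd = ccd)
  )
}

#' Generate toy sequence families with controlled identity
#'
#' Independent random ancestors found each family; members are per-site
#' substituted at `mutation_rate`, so the expected intra-family identity is
#' about `1 - mutation_rate` and inter-family identity is background
#' (about 5%).
#'
#' @param seed Integer seed.
#' @param n_families Number of families.
#' @param members Members per family.
#' @param seq_len Sequence length.
#' @param mutation_rate Per-site substitution rate within a family; each
#'   member carries exactly `round(mutation_rate * seq_len)` substitutions,
#'   so any two members are at least `1 - 2 * mutation_rate` identical.
#' @return List with `seqs` (named character vector, names
#'   `f<i>_m<j>`) and `manifest` (family of each sequence).
#' @export
gen_sequence_families <- function(seed, n_families = 3, members = 4,
                                  seq_len = 80, mutation_rate = 0.02) {
  set.seed(as.integer(seed))
  seqs <- character(0)
  fam <- character(0)
  k <- round(mutation_rate * seq_len)
  for (f in seq_len(n_families)) {
    anc <- sample(.AA20, seq_len, replace = TRUE)
    for (m in seq_len(members)) {
      s <- anc
      hit <- sample.int(seq_len, k)
      if (k > 0)
        s[hit] <- vapply(s[hit],
                         function(a) sample(setdiff(.AA20, a), 1), "")
      nm <- sprintf("f%d_m%d", f, m)
      seqs[nm] <- paste(s, collapse = "")
      fam[nm] <- sprintf("f%d", f)
    }
  }
  list(seqs = seqs, manifest = list(seed = seed, family = fam,
                                    mutation_rate = mutation_rate))
}

#' Generate a PSI-BLAST-style ASCII PSSM fixture
#'
#' Writes the `-out_ascii_pssm` dialect (header, 40-letter column header,
#' one row per residue with 20 log-odds integers followed by 20
#' weighted-percentage columns, trailing statistics) for a random integer
#' profile, so the parser is exercised against the real layout.
#'
#' @param seed Integer seed.
#' @param L Sequence length.
#' @return List with `text` (lines), `scores` (the planted L x 20 matrix)
#'   and `sequence`.
#' @export
gen_pssm_text <- function(seed, L = 8) {
  set.seed(as.integer(seed))
  scores <- matrix(sample(-8:11, L * 20, replace = TRUE), L, 20)
  seqv <- sample(.AA20, L, replace = TRUE)
  pct <- matrix(sample(0:50, L * 20, replace = TRUE), L, 20)
  hdr2 <- paste0("            ",
                 paste(sprintf("%3s", .AA20), collapse = ""), "  ",
                 paste(sprintf("%3s", .AA20), collapse = ""))
  rows <- vapply(seq_len(L), function(i) {
    paste0(sprintf("%5d %s  ", i, seqv[i]),
           paste(sprintf("%3d", scores[i, ]), collapse = ""), "  ",
           paste(sprintf("%3d", pct[i, ]), collapse = ""),
           sprintf("  %5.2f %8.2f", 0.36, 0.08))
  }, "")
  text <- c(
    "",
    "Last position-specific scoring matrix computed, weighted, and rounded",
    hdr2, rows, "",
    "                      K         Lambda",
    "Standard Ungapped    0.1342     0.3176")
  list(text = text, scores = scores, sequence = paste(seqv, collapse = ""))
}

#' Generate a two-class Gaussian feature cloud in window space
#'
#' Two multivariate normal classes in `w * 21` dimensions whose means are
#' `separation_sigma` standard deviations apart along a seeded random unit
#' direction over the profile-score coordinates; spacer coordinates carry
#' the all-interior window pattern (all zero).
#'
#' @param seed Integer seed.
#' @param n_pos,n_neg Examples per class.
#' @param w Odd window size (sets the dimension).
#' @param separation_sigma Class-mean separation in noise standard
#'   deviations; 0 gives a null (inseparable) dataset.
#' @return List with `dataset` (a `pl_dataset`) and `manifest` (seed,
#'   separation, direction).
#' @export
gen_labeled_features <- function(seed, n_pos = 100, n_neg = 100, w = 9,
                                 separation_sigma = 4) {
  stopifnot(separation_sigma >= 0, w %% 2 == 1)
  set.seed(as.integer(seed))
  d <- w * 21
  spacer_cols <- 21 * seq_len(w)
  score_cols <- setdiff(seq_len(d), spacer_cols)
  dir <- stats::rnorm(length(score_cols))
  dir <- dir / sqrt(sum(dir^2))
  n <- n_pos + n_neg
  y <- rep(c(1L, 0L), c(n_pos, n_neg))
  X <- matrix(0, n, d)
  noise <- matrix(stats::rnorm(n * length(score_cols)), n)
  shift <- outer(ifelse(y == 1, separation_sigma / 2, -separation_sigma / 2),
                 dir)
  X[, score_cols] <- noise + shift
  dataset <- structure(
    list(X = X, y = y,
         meta = data.frame(seq_id = sprintf("synth_%04d", seq_len(n)),
                           position = seq_len(n)),
         w = w, scale = 1),
    class = "pl_dataset"
  )
  list(dataset = dataset,
       manifest = list(seed = seed, n_pos = n_pos, n_neg = n_neg, w = w,
                       separation_sigma = separation_sigma))
}

#' Generate a profile corpus whose separability is controlled by window size
#'
#' Builds one labeled position per toy sequence; the class signal lives only
#' in the profile rows at offset +/- `signal_offset` from the labeled
#' position, so a window must span at least `2 * signal_offset + 1` residues
#' before any classifier can separate the classes. Binding-labeled sequences
#' carry the signal at `+delta` or `-delta` (alternating), non-binding ones
#' carry none, so the positive class is bimodal around the negatives: a
#' near-linear decision function (huge kernel width) cannot separate it, a
#' tiny width overfits, and only an intermediate Gaussian width scores well.
#' Gaussian row noise keeps the attainable AUC below 1. This is the tunable
#' fixture for optimizer tests: the w gene gates attainable fitness and the
#' kernel-width gene has a genuine interior optimum.
#'
#' @param seed Integer seed.
#' @param n_seqs Number of sequences (half labeled positive); even.
#' @param seq_len Toy sequence length.
#' @param signal_offset Offset of the informative rows from the labeled
#'   position.
#' @param delta Signal magnitude added to the informative rows.
#' @param n_signal_cols How many profile columns carry the signal.
#' @param scale Score divisor recorded on the corpus (1 = already scaled).
#' @return List with `corpus` (a `pl_corpus`) and `manifest` (seed, the
#'   minimum window size `w_needed`, delta).
#' @export
gen_offset_corpus <- function(seed, n_seqs = 80, seq_len = 15,
                              signal_offset = 3, delta = 2,
                              n_signal_cols = 4, scale = 1) {
  stopifnot(n_seqs %% 2 == 0, seq_len >= 2 * signal_offset + 1)
  set.seed(as.integer(seed))
  center <- (seq_len + 1) %/% 2
  labelsets <- list()
  profiles <- list()
  for (i in seq_len(n_seqs)) {
    positive <- i <= n_seqs / 2
    sid <- sprintf("t%03d", i)
    scores <- matrix(stats::rnorm(seq_len * 20), seq_len, 20)
    sgn <- if (!positive) 0 else if (i %% 2 == 0) delta else -delta
    for (off in c(-signal_offset, signal_offset)) {
      scores[center + off, seq_len(n_signal_cols)] <-
        scores[center + off, seq_len(n_signal_cols)] + sgn
    }
    profiles[[sid]] <- .new_profile(scores, sid)
    labelsets[[length(labelsets) + 1]] <- structure(
      list(seq_id = sid,
           positives = if (positive) center else integer(0),
           negatives = if (positive) integer(0) else center),
      class = "pl_labelset"
    )
  }
  list(corpus = feature_corpus(labelsets, profiles, scale = scale),
       manifest = list(seed = seed, w_needed = 2 * signal_offset + 1,
                       delta = delta, n_seqs = n_seqs))
}
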