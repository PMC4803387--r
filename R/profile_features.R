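# Sequence-profile construction and sliding-window feature encoding.

#' PSI-BLAST amino-acid column ordering
#'
#' The fixed 20-letter ordering used for all profile matrices in the package.
#' @return Character vector of 20 one-letter codes.
#' @export
aa_columns <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")
}

.new_profile <- function(scores, seq_id, sequence = NULL) {
  colnames(scores) <- aa_columns()
  structure(list(seq_id = seq_id, scores = scores, sequence = sequence),
            class = "pl_profile")
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` dialect: header lines, a column-letter header,
#' then one row per residue carrying position, residue letter, 20 log-odds
#' integers and (usually) 20 weighted-percentage columns plus trailing
#' statistics. Only the first 20 numeric columns (log-odds) are kept.
#'
#' @param lines Character vector of lines, a single string, or a file path.
#' @param seq_id Identifier attached to the profile.
#' @param sequence Optional amino-acid string cross-checked against the
#'   residue letters in the file.
#' @return A `pl_profile`: list with `seq_id`, L x 20 `scores` matrix
#'   (columns in [aa_columns()] order) and the residue `sequence`.
#' @export
parse_psiblast_pssm <- function(lines, seq_id = "query", sequence = NULL) {
  if (length(lines) == 1 && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE)
  } else if (length(lines) == 1 && grepl("\n", lines, fixed = TRUE)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  }
  toks <- lapply(strsplit(trimws(lines), "\\s+"), function(t) t[t != ""])
  is_row <- vapply(toks, function(t) {
    length(t) >= 22 && grepl("^[0-9]+$", t[1]) && grepl("^[A-Z]$", t[2]) &&
      !anyNA(suppressWarnings(as.numeric(t[3:22])))
  }, TRUE)
  rows <- toks[is_row]
  if (!length(rows)) stop("not a PSI-BLAST ASCII PSSM: no profile rows found",
                          call. = FALSE)
  pos <- vapply(rows, function(t) as.integer(t[1]), 0L)
  if (!identical(pos, seq_along(pos)))
    stop("PSSM rows are not consecutively numbered from 1", call. = FALSE)
  letters_ <- vapply(rows, function(t) t[2], "")
  ncols <- vapply(rows, length, 0L)
  if (length(unique(ncols)) > 1)
    stop("ragged PSSM body: inconsistent column counts", call. = FALSE)
  scores <- t(vapply(rows, function(t) as.numeric(t[3:22]), numeric(20)))
  seq_in_file <- paste(letters_, collapse = "")
  if (!is.null(sequence) && !identical(seq_in_file, sequence))
    stop("PSSM residue letters do not match the supplied sequence",
         call. = FALSE)
  .new_profile(scores, seq_id, seq_in_file)
}

#' Compute a profile from a multiple sequence alignment
#'
#' The first record is the ungapped-reference master sequence; profile rows
#' are emitted for its non-gap columns only. The score for amino acid `a` at
#' a column is `log2((count(a) + pc * bg) / ((N + pc) * bg))` with a uniform
#' background `bg = 1/20`, `N` the number of residues observed at the column
#' and `pc` the pseudocount mass. Gaps and non-standard letters are excluded
#' from the counts.
#'
#' @param msa Named character vector of aligned sequences (equal lengths,
#'   `-` for gaps), or a path to an aligned FASTA file.
#' @param pseudocount Positive pseudocount mass; default 1.
#' @param seq_id Identifier for the resulting profile (defaults to the
#'   master record's name).
#' @return A `pl_profile` over the master sequence.
#' @export
profile_from_alignment <- function(msa, pseudocount = 1, seq_id = NULL) {
  if (is.character(msa) && length(msa) == 1 && file.exists(msa))
    msa <- read_fasta(msa)
  stopifnot(length(msa) >= 1, pseudocount > 0)
  if (length(unique(nchar(msa))) != 1)
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  if (is.null(seq_id)) seq_id <- names(msa)[1] %||% "query"
  aa <- aa_columns()
  mat <- do.call(rbind, strsplit(unname(msa), ""))
  master <- mat[1, ]
  keep <- which(master != "-")
  bg <- 1 / 20
  scores <- matrix(0, length(keep), 20)
  for (r in seq_along(keep)) {
    col <- mat[, keep[r]]
    col <- col[col %in% aa]
    n <- length(col)
    cnt <- tabulate(match(col, aa), 20)
    scores[r, ] <- log2((cnt + pseudocount * bg) / ((n + pseudocount) * bg))
  }
  .new_profile(scores, seq_id, paste(master[keep], collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode one residue as a w x 21 sliding-window feature vector
#'
#' The window covers the `w` consecutive positions centred on the target
#' residue. Each slot contributes its 20 profile scores plus one terminal
#' spacer flag: slots falling outside the sequence (beyond the N or C
#' terminus) carry 20 zeros and spacer 1, all in-sequence slots carry the
#' profile row and spacer 0.
#'
#' @param profile A `pl_profile`.
#' @param center 1-based target position.
#' @param w Odd window size >= 1.
#' @return Numeric vector of length `w * 21`, slot-major (20 scores then the
#'   spacer flag per slot).
#' @export
window_encode <- function(profile, center, w) {
  stopifnot(inherits(profile, "pl_profile"))
  if (w %% 2 != 1 || w < 1) stop("window size w must be odd and >= 1",
                                 call. = FALSE)
  L <- nrow(profile$scores)
  if (center < 1 || center > L)
    stop("center position outside the sequence", call. = FALSE)
  half <- (w - 1) / 2
  slots <- (center - half):(center + half)
  out <- numeric(w * 21)
  for (k in seq_along(slots)) {
    p <- slots[k]
    base <- (k - 1) * 21
    if (p >= 1 && p <= L) {
      out[base + 1:20] <- profile$scores[p, ]
    } else {
      out[base + 21] <- 1
    }
  }
  out
}

#' Vectorize labeled residue sets into a feature matrix
#'
#' One `(window vector, label)` example per labeled position, in
#' deterministic (seq_id, position) order. Profile scores are divided by
#' `scale` (default 10) so RBF kernels see a bounded range; spacer flags are
#' never scaled.
#'
#' @param labelsets List of `pl_labelset` (see [assemble_dataset()]).
#' @param profiles Named list of `pl_profile`, keyed by seq_id.
#' @param w Odd window size.
#' @param scale Positive divisor applied to profile scores; 1 disables.
#' @return A `pl_dataset`: list with feature matrix `X` (n x w*21), integer
#'   labels `y` (1 = binding), `meta` data frame (seq_id, position), `w` and
#'   `scale`.
#' @export
vectorize_dataset <- function(labelsets, profiles, w, scale = 10) {
  stopifnot(scale > 0)
  if (!length(labelsets)) {
    return(structure(list(X = matrix(0, 0, w * 21), y = integer(0),
                          meta = data.frame(seq_id = character(0),
                                            position = integer(0)),
                          w = w, scale = scale),
                     class = "pl_dataset"))
  }
  rows <- do.call(rbind, lapply(labelsets, function(l) {
    data.frame(seq_id = l$seq_id,
               position = c(l$positives, l$negatives),
               label = rep(c(1L, 0L), c(length(l$positives),
                                        length(l$negatives))),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$seq_id, rows$position), , drop = FALSE]
  missing <- setdiff(unique(rows$seq_id), names(profiles))
  if (length(missing))
    stop("no profile for sequence(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- matrix(0, nrow(rows), w * 21)
  spacer_cols <- 21 * seq_len(w)
  for (i in seq_len(nrow(rows))) {
    v <- window_encode(profiles[[rows$seq_id[i]]], rows$position[i], w)
    v[-spacer_cols] <- v[-spacer_cols] / scale
    X[i, ] <- v
  }
  structure(list(X = X, y = rows$label,
                 meta = rows[c("seq_id", "position")], w = w, scale = scale),
            class = "pl_dataset")
}

#' Bundle label sets and profiles for window-size-aware tuning
#'
#' A corpus defers feature encoding so the optimizer can re-window at any
#' candidate `w`; [as_dataset()] materializes it.
#'
#' @param labelsets List of `pl_labelset`.
#' @param profiles Named list of `pl_profile`.
#' @param scale Score divisor passed through to [vectorize_dataset()].
#' @return A `pl_corpus`.
#' @export
feature_corpus <- function(labelsets, profiles, scale = 10) {
  structure(list(labelsets = labelsets, profiles = profiles, scale = scale),
            class = "pl_corpus")
}

#' Materialize a corpus (or pass a dataset through) at window size w
#' @param data A `pl_corpus` or `pl_dataset`.
#' @param w Odd window size (ignored for an already-encoded dataset).
#' @return A `pl_dataset`.
#' @export
as_dataset <- function(data, w = NULL) {
  if (inherits(data, "pl_dataset")) return(data)
  if (inherits(data, "pl_corpus")) {
    stopifnot(!is.null(w))
    return(vectorize_dataset(data$labelsets, data$profiles, w, data$scale))
  }
  stop("expected a pl_dataset or pl_corpus", call. = FALSE)
}

#' @export
print.pl_profile <- function(x, ...) {
  cat(sprintf("pl_profile '%s': %d positions x 20 scores\n", x$seq_id,
              nrow(x$scores)))
  invisible(x)
}

#' @export
print.pl_dataset <- function(x, ...) {
  cat(sprintf("pl_dataset: %d examples (%d positive), w = %d, %d features\n",
              length(x$y), sum(x$y), x$w, ncol(x$X)))
  invisible(x)
}

#' Write a feature dataset as TSV with a JSON sidecar
#'
#' The TSV holds seq_id, position, label and the w*21 feature columns; the
#' sidecar records w, scale and the amino-acid column order.
#' @param dataset A `pl_dataset`.
#' @param path Output TSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  tab <- cbind(dataset$meta, label = dataset$y, as.data.frame(dataset$X))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(w = dataset$w, scale = dataset$scale, columns = aa_columns(),
         n = length(dataset$y)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
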