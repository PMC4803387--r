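# Non-redundant positive/negative residue dataset construction.

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Pairwise sequence identity and coverage
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62, gap open 11 / extend 1.
#' Identity is matches over alignment columns after stripping terminal gaps;
#' coverage is the fraction of the shorter sequence inside the stripped
#' alignment (the convention of greedy clustering tools).
#'
#' @param a,b Amino-acid strings (20-letter alphabet plus X).
#' @return List with `identity` and `coverage`, both fractions in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global"
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gap <- p == "-" | s == "-"
  inner <- which(!gap)
  if (!length(inner)) return(list(identity = 0, coverage = 0))
  span <- inner[1]:inner[length(inner)]
  idty <- mean(p[span] == s[span])
  shorter <- if (nchar(a) <= nchar(b)) p else s
  cov <- sum(shorter[span] != "-") / min(nchar(a), nchar(b))
  list(identity = idty, coverage = cov)
}

#' Remove sequence redundancy by greedy incremental clustering
#'
#' Sequences are sorted by decreasing length (stable) and each one joins the
#' first existing cluster whose representative it matches at
#' `>= identity_threshold` identity over an alignment covering
#' `>= coverage_threshold` of the shorter sequence, otherwise it founds a new
#' cluster. Defaults reproduce the usual 90% identity / 50% coverage
#' redundancy condition.
#'
#' @param seqs Named character vector of sequences (names are sequence ids).
#' @param identity_threshold,coverage_threshold Fractions in (0, 1\].
#' @return Named character vector of cluster representatives, in input order.
#'   Attribute `clusters` maps each input id to its representative id.
#' @export
remove_redundancy <- function(seqs, identity_threshold = 0.90,
                              coverage_threshold = 0.50) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1)
  if (!length(seqs)) return(seqs)
  if (is.null(names(seqs)) || anyNA(names(seqs)))
    stop("sequences must be named", call. = FALSE)
  ord <- order(-nchar(seqs))
  reps <- integer(0) # indices into seqs
  member_of <- setNames(character(length(seqs)), names(seqs))
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      al <- pairwise_identity(seqs[[i]], seqs[[r]])
      if (al$identity >= identity_threshold &&
          al$coverage >= coverage_threshold) {
        member_of[names(seqs)[i]] <- names(seqs)[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      member_of[names(seqs)[i]] <- names(seqs)[i]
    }
  }
  out <- seqs[sort(reps)]
  attr(out, "clusters") <- member_of
  out
}

#' Negative (non-binding) residue band around each positive
#'
#' Non-binding training residues are those at sequence offsets
#' `min_offset`..`max_offset` on either side of each binding residue, clipped
#' to the sequence and with all positives removed (positives win).
#'
#' @param positives Integer set of 1-based binding positions.
#' @param seq_len Sequence length.
#' @param min_offset,max_offset Band limits in residues; defaults 5 and 25.
#' @return Sorted integer vector of negative positions.
#' @export
make_negative_set <- function(positives, seq_len, min_offset = 5,
                              max_offset = 25) {
  stopifnot(min_offset >= 1, min_offset <= max_offset, seq_len >= 1)
  positives <- unique(as.integer(positives))
  if (!length(positives)) return(integer(0))
  if (any(positives < 1 | positives > seq_len))
    stop("positive positions outside [1, seq_len]", call. = FALSE)
  offs <- min_offset:max_offset
  cand <- unique(c(outer(positives, offs, `+`), outer(positives, offs, `-`)))
  sort(setdiff(cand[cand >= 1 & cand <= seq_len], positives))
}

#' Assemble labeled residue sets from annotations and sequences
#'
#' Applies redundancy removal to the sequences first; labels are emitted only
#' for surviving representatives. Positives are the union of binding residues
#' across all instances of the target ligand group on that sequence; the
#' negative band rule supplies negatives.
#'
#' @param annotations Data frame with columns `seq_id`, `residue_index` and
#'   `ccd_code` (as produced by [annotations_table()] plus a seq_id column,
#'   conventionally `<pdb_id>_<chain>`).
#' @param seqs Named character vector of sequences covering every annotated
#'   seq_id.
#' @param ligands Character vector of component codes forming the target
#'   ligand group; `NULL` keeps all.
#' @param identity_threshold,coverage_threshold Redundancy thresholds.
#' @param min_offset,max_offset Negative band limits.
#' @return List of label sets, each `list(seq_id, positives, negatives)`,
#'   class `pl_labelset`; ordered by seq_id.
#' @export
assemble_dataset <- function(annotations, seqs, ligands = NULL,
                             identity_threshold = 0.90,
                             coverage_threshold = 0.50,
                             min_offset = 5, max_offset = 25) {
  need <- c("seq_id", "residue_index")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns seq_id and residue_index", call. = FALSE)
  if (!is.null(ligands) && "ccd_code" %in% names(annotations))
    annotations <- annotations[annotations$ccd_code %in% ligands, , drop = FALSE]
  missing <- setdiff(unique(annotations$seq_id), names(seqs))
  if (length(missing))
    stop("annotations reference sequences absent from FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!nrow(annotations)) return(list())

  reps <- remove_redundancy(seqs, identity_threshold, coverage_threshold)
  keep <- intersect(unique(annotations$seq_id), names(reps))
  out <- lapply(sort(keep), function(sid) {
    pos <- sort(unique(annotations$residue_index[annotations$seq_id == sid]))
    L <- nchar(seqs[[sid]])
    pos <- pos[pos <= L]
    structure(
      list(seq_id = sid, positives = pos,
           negatives = make_negative_set(pos, L, min_offset, max_offset)),
      class = "pl_labelset"
    )
  })
  out[vapply(out, function(l) length(l$positives) > 0, TRUE)]
}

#' Write a labeled residue dataset as TSV
#'
#' One row per labeled residue: seq_id, position, label (1 = binding).
#' @param labelsets List of `pl_labelset`.
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_labelsets <- function(labelsets, path) {
  rows <- lapply(labelsets, function(l) {
    data.frame(seq_id = l$seq_id,
               position = c(l$positives, l$negatives),
               label = rep(c(1L, 0L), c(length(l$positives),
                                        length(l$negatives))))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(seq_id = character(0), position = integer(0),
                      label = integer(0))
  tab <- tab[order(tab$seq_id, tab$position), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Read/write FASTA sequence sets
#'
#' Thin wrappers over Biostrings keeping the package's plain named character
#' vector convention.
#' @param path FASTA file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  setNames(as.character(s), sub(" .*", "", names(s)))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}
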