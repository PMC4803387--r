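# Structure parsing and ligand-binding residue extraction.

# Residue names folded into the polymer chain even when they appear as
# HETATM records (selenomethionine is the common case in X-ray entries).
.POLYMER_RES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE"
)
.WATER_RES <- c("HOH", "DOD")

#' Default buffer / crystallization-medium component codes
#'
#' Chemical components commonly present as crystallization buffer rather than
#' biologically relevant ligands. The list is a package choice (user-editable),
#' not a fixed standard; waters are always discarded at parse time.
#'
#' @return Character vector of 2-3 letter chemical component codes.
#' @export
default_buffer_ccds <- function() {
  c("HOH", "GOL", "EDO", "SO4", "PO4", "CL", "NA")
}

.substr_trim <- function(x, a, b) {
  trimws(substr(x, a, min(b, nchar(x))))
}

.num_field <- function(x, a, b, lineno, what) {
  v <- suppressWarnings(as.numeric(.substr_trim(x, a, b)))
  if (any(is.na(v))) {
    bad <- lineno[is.na(v)][1]
    stop(sprintf("malformed %s field in PDB record at line %d", what, bad),
         call. = FALSE)
  }
  v
}

#' Parse a PDB-format protein-ligand complex
#'
#' Reads fixed-column `ATOM`/`HETATM`/`CONECT`/`LINK` records. Waters are
#' discarded, standard residues appearing as `HETATM` (e.g. MSE) are folded
#' into the polymer, remaining `HETATM` groups become ligand instances keyed
#' by (component code, chain, residue number, insertion code). Only the first
#' model of a multi-model file is kept, and only the first alternate location
#' per atom name within a residue.
#'
#' @param lines Character vector of PDB lines, a single string with embedded
#'   newlines, or a path to an existing file.
#' @return An object of class `pl_structure`: a list with `atoms` (data frame
#'   with serial, name, resname, chain, resseq, icode, x, y, z, element, kind,
#'   res_index, lig_id), `chains` (per-chain residue tables mapping the dense
#'   1-based `res_index` back to author numbering), `ligands` (one row per
#'   ligand instance) and `covalent_links` (two-column matrix of atom serials).
#' @export
parse_pdb <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE)
  } else if (length(lines) == 1 && grepl("\n", lines, fixed = TRUE)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  }
  rec <- substr(lines, 1, 6)

  # first model only
  mstart <- which(trimws(rec) == "MODEL")
  if (length(mstart) > 1) {
    mend <- which(trimws(rec) == "ENDMDL")
    stop_at <- if (length(mend)) mend[1] else length(lines)
    keep <- seq_len(length(lines)) <= stop_at |
      !(trimws(rec) %in% c("ATOM", "HETATM", "ANISOU", "TER"))
    lines <- lines[keep]
    rec <- substr(lines, 1, 6)
  }

  is_atom <- rec == "ATOM  " | rec == "HETATM"
  ln <- which(is_atom)
  if (!length(ln)) stop("empty structure: no ATOM or HETATM records", call. = FALSE)
  al <- lines[ln]

  atoms <- data.frame(
    serial = as.integer(.num_field(al, 7, 11, ln, "serial")),
    name = .substr_trim(al, 13, 16),
    alt = .substr_trim(al, 17, 17),
    resname = .substr_trim(al, 18, 20),
    chain = .substr_trim(al, 22, 22),
    resseq = as.integer(.num_field(al, 23, 26, ln, "residue number")),
    icode = .substr_trim(al, 27, 27),
    x = .num_field(al, 31, 38, ln, "x coordinate"),
    y = .num_field(al, 39, 46, ln, "y coordinate"),
    z = .num_field(al, 47, 54, ln, "z coordinate"),
    element = .substr_trim(al, 77, 78),
    hetatm = substr(al, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(atoms$serial))
    stop("duplicate atom serial numbers within model", call. = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates", call. = FALSE)

  # waters are never ligands; a water-only file yields an empty structure
  atoms <- atoms[!(atoms$resname %in% .WATER_RES), , drop = FALSE]

  # first altLoc per (chain, resseq, icode, name)
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$resname, atoms$name)
  atoms <- atoms[!duplicated(key), , drop = FALSE]

  atoms$kind <- ifelse(atoms$resname %in% .POLYMER_RES, "polymer", "hetero")
  atoms$kind[atoms$hetatm & !(atoms$resname %in% .POLYMER_RES)] <- "hetero"

  # dense residue indices per chain, by order of appearance
  atoms$res_index <- rep(NA_integer_, nrow(atoms))
  atoms$lig_id <- rep(NA_integer_, nrow(atoms))
  chains <- list()
  pol <- atoms$kind == "polymer"
  if (any(pol)) {
    rkey <- paste(atoms$chain, atoms$resseq, atoms$icode)
    for (ch in unique(atoms$chain[pol])) {
      sel <- pol & atoms$chain == ch
      ord_keys <- unique(rkey[sel])
      idx <- match(rkey[sel], ord_keys)
      atoms$res_index[sel] <- idx
      first <- !duplicated(rkey[sel])
      chains[[ch]] <- data.frame(
        res_index = idx[first],
        resname = atoms$resname[sel][first],
        resseq = atoms$resseq[sel][first],
        icode = atoms$icode[sel][first],
        stringsAsFactors = FALSE
      )
    }
  }

  het <- atoms$kind == "hetero"
  ligands <- data.frame(
    lig_id = integer(0), ccd = character(0), chain = character(0),
    resseq = integer(0), icode = character(0), n_atoms = integer(0),
    stringsAsFactors = FALSE
  )
  if (any(het)) {
    lkey <- paste(atoms$resname[het], atoms$chain[het], atoms$resseq[het],
                  atoms$icode[het])
    uk <- unique(lkey)
    atoms$lig_id[het] <- match(lkey, uk)
    first <- !duplicated(lkey)
    ligands <- data.frame(
      lig_id = seq_along(uk),
      ccd = atoms$resname[het][first],
      chain = atoms$chain[het][first],
      resseq = atoms$resseq[het][first],
      icode = atoms$icode[het][first],
      n_atoms = as.integer(table(factor(match(lkey, uk), seq_along(uk)))),
      stringsAsFactors = FALSE
    )
  }

  links <- .parse_links(lines, rec, atoms)
  atoms$hetatm <- NULL
  structure(
    list(atoms = atoms, chains = chains, ligands = ligands,
         covalent_links = links),
    class = "pl_structure"
  )
}

.parse_links <- function(lines, rec, atoms) {
  links <- matrix(integer(0), ncol = 2)
  con <- lines[rec == "CONECT"]
  if (length(con)) {
    pieces <- lapply(con, function(l) {
      starts <- c(7, 12, 17, 22, 27)
      v <- suppressWarnings(as.integer(vapply(
        starts, function(s) .substr_trim(l, s, s + 4), "")))
      v <- v[!is.na(v)]
      if (length(v) >= 2) cbind(v[1], v[-1]) else NULL
    })
    links <- do.call(rbind, c(list(links), pieces))
  }
  lnk <- lines[rec == "LINK  "]
  if (length(lnk)) {
    for (l in lnk) {
      s1 <- .resolve_atom(atoms, .substr_trim(l, 13, 16), .substr_trim(l, 18, 20),
                          .substr_trim(l, 22, 22), .substr_trim(l, 23, 26),
                          .substr_trim(l, 27, 27))
      s2 <- .resolve_atom(atoms, .substr_trim(l, 43, 46), .substr_trim(l, 48, 50),
                          .substr_trim(l, 52, 52), .substr_trim(l, 53, 56),
                          .substr_trim(l, 57, 57))
      if (!is.na(s1) && !is.na(s2)) links <- rbind(links, c(s1, s2))
    }
  }
  # keep only links between atoms that survived parsing
  if (nrow(links)) {
    keep <- links[, 1] %in% atoms$serial & links[, 2] %in% atoms$serial
    links <- links[keep, , drop = FALSE]
  }
  links
}

.resolve_atom <- function(atoms, name, resname, chain, resseq, icode) {
  hit <- which(atoms$name == name & atoms$resname == resname &
                 atoms$chain == chain &
                 atoms$resseq == suppressWarnings(as.integer(resseq)) &
                 atoms$icode == icode)
  if (length(hit)) atoms$serial[hit[1]] else NA_integer_
}

#' Build an octree over a point cloud
#'
#' Recursive eight-way spatial subdivision used for radius queries against
#' atom coordinates. Degenerate clouds (a single atom, collinear points) are
#' allowed.
#'
#' @param coords Numeric matrix with 3 columns (x, y, z), one row per atom.
#' @param leaf_capacity Maximum points held in a leaf before splitting.
#' @param max_depth Maximum subdivision depth.
#' @return An object of class `pl_octree`.
#' @export
build_octree <- function(coords, leaf_capacity = 8, max_depth = 12) {
  coords <- as.matrix(coords)
  if (!nrow(coords)) stop("octree requires at least one point", call. = FALSE)
  if (leaf_capacity < 1) stop("leaf_capacity must be >= 1", call. = FALSE)
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  root <- .oct_build(coords, seq_len(nrow(coords)), lo, hi, leaf_capacity,
                     max_depth, 0L)
  structure(list(root = root, coords = coords), class = "pl_octree")
}

.oct_build <- function(coords, idx, lo, hi, cap, maxd, depth) {
  if (length(idx) <= cap || depth >= maxd) {
    return(list(leaf = TRUE, idx = idx, lo = lo, hi = hi))
  }
  mid <- (lo + hi) / 2
  sub <- coords[idx, , drop = FALSE]
  oct <- 1L + (sub[, 1] > mid[1]) + 2L * (sub[, 2] > mid[2]) +
    4L * (sub[, 3] > mid[3])
  children <- vector("list", 8)
  for (o in unique(oct)) {
    bits <- c((o - 1L) %% 2L, ((o - 1L) %/% 2L) %% 2L, (o - 1L) %/% 4L)
    clo <- ifelse(bits == 1, mid, lo)
    chi <- ifelse(bits == 1, hi, mid)
    children[[o]] <- .oct_build(coords, idx[oct == o], clo, chi, cap, maxd,
                                depth + 1L)
  }
  list(leaf = FALSE, children = children, lo = lo, hi = hi)
}

#' Radius query against an octree
#'
#' @param tree A `pl_octree` from [build_octree()].
#' @param point Numeric length-3 query point.
#' @param r Query radius in the same units as the coordinates (angstroms).
#' @return Integer indices (rows of the coordinate matrix the tree was built
#'   on) of all points with Euclidean distance <= `r` from `point`.
#' @export
octree_query <- function(tree, point, r) {
  stopifnot(inherits(tree, "pl_octree"), length(point) == 3, r >= 0)
  sort(.oct_query(tree$root, tree$coords, as.numeric(point), r * r))
}

.oct_query <- function(node, coords, p, r2) {
  gap <- pmax(node$lo - p, p - node$hi, 0)
  if (sum(gap * gap) > r2) return(integer(0))
  if (node$leaf) {
    sub <- coords[node$idx, , drop = FALSE]
    d2 <- (sub[, 1] - p[1])^2 + (sub[, 2] - p[2])^2 + (sub[, 3] - p[3])^2
    return(node$idx[d2 <= r2])
  }
  unlist(lapply(node$children, function(ch) {
    if (is.null(ch)) integer(0) else .oct_query(ch, coords, p, r2)
  }), use.names = FALSE)
}

#' Remove covalently attached ligands
#'
#' Drops every ligand instance with a covalent bond (CONECT/LINK record) from
#' one of its atoms to a polymer atom or to an atom of a different ligand
#' instance. Bonds internal to a ligand are ignored.
#'
#' @param structure A `pl_structure`.
#' @return The structure with the offending ligand instances (and their
#'   atoms) removed.
#' @export
exclude_covalent_ligands <- function(structure) {
  stopifnot(inherits(structure, "pl_structure"))
  links <- structure$covalent_links
  if (!nrow(structure$ligands) || is.null(links) || !nrow(links)) {
    return(structure)
  }
  atoms <- structure$atoms
  lig_of <- atoms$lig_id[match(c(links[, 1], links[, 2]), atoms$serial)]
  lig_of <- matrix(lig_of, ncol = 2)
  # a link is "external" for a ligand when the partner is not the same ligand
  drop <- unique(c(
    lig_of[!is.na(lig_of[, 1]) &
             (is.na(lig_of[, 2]) | lig_of[, 2] != lig_of[, 1]), 1],
    lig_of[!is.na(lig_of[, 2]) &
             (is.na(lig_of[, 1]) | lig_of[, 1] != lig_of[, 2]), 2]
  ))
  if (!length(drop)) return(structure)
  structure$ligands <- structure$ligands[
    !(structure$ligands$lig_id %in% drop), , drop = FALSE]
  structure$atoms <- atoms[is.na(atoms$lig_id) | !(atoms$lig_id %in% drop), ,
                           drop = FALSE]
  structure
}

#' Extract ligand-binding residues by atomic distance
#'
#' A polymer residue is binding when at least one of its atoms lies within
#' `cutoff_A` angstroms of any atom of the ligand instance. Distances are
#' found through an octree over the polymer atoms; the result is identical to
#' a brute-force all-pairs scan.
#'
#' @param structure A `pl_structure` (after covalent exclusion).
#' @param lig_id Integer id of the ligand instance (row of
#'   `structure$ligands`).
#' @param cutoff_A Distance cutoff in angstroms, in \[3.5, 6\]; default 5.
#' @param octree Optional pre-built octree over the polymer atoms (reused
#'   across ligands of the same structure).
#' @return Object of class `pl_binding`: list with `lig_id`, `ccd`,
#'   `cutoff_A` and `residues`, a data frame (chain, res_index, resseq,
#'   icode, min_distance_A) sorted by chain then residue index.
#' @export
extract_binding_residues <- function(structure, lig_id, cutoff_A = 5,
                                     octree = NULL) {
  stopifnot(inherits(structure, "pl_structure"))
  if (cutoff_A < 3.5 || cutoff_A > 6)
    stop("cutoff_A must lie in [3.5, 6]", call. = FALSE)
  lrow <- structure$ligands[structure$ligands$lig_id == lig_id, , drop = FALSE]
  if (!nrow(lrow)) stop(sprintf("ligand id %s not found", lig_id), call. = FALSE)

  atoms <- structure$atoms
  pol <- which(atoms$kind == "polymer")
  la <- atoms[!is.na(atoms$lig_id) & atoms$lig_id == lig_id, , drop = FALSE]
  res <- data.frame(chain = character(0), res_index = integer(0),
                    resseq = integer(0), icode = character(0),
                    min_distance_A = numeric(0), stringsAsFactors = FALSE)
  if (length(pol) && nrow(la)) {
    pc <- as.matrix(atoms[pol, c("x", "y", "z")])
    if (is.null(octree)) octree <- build_octree(pc)
    mind <- list()
    for (i in seq_len(nrow(la))) {
      p <- c(la$x[i], la$y[i], la$z[i])
      hits <- octree_query(octree, p, cutoff_A)
      if (!length(hits)) next
      d <- sqrt(rowSums((pc[hits, , drop = FALSE] -
                           matrix(p, length(hits), 3, byrow = TRUE))^2))
      key <- paste(atoms$chain[pol[hits]], atoms$res_index[pol[hits]])
      for (k in seq_along(hits)) {
        cur <- mind[[key[k]]]
        if (is.null(cur) || d[k] < cur$d) {
          mind[[key[k]]] <- list(d = d[k], at = pol[hits[k]])
        }
      }
    }
    if (length(mind)) {
      at <- vapply(mind, function(e) e$at, 0L)
      res <- data.frame(
        chain = atoms$chain[at],
        res_index = atoms$res_index[at],
        resseq = atoms$resseq[at],
        icode = atoms$icode[at],
        min_distance_A = vapply(mind, function(e) e$d, 0),
        stringsAsFactors = FALSE
      )
      res <- res[order(res$chain, res$res_index), , drop = FALSE]
      rownames(res) <- NULL
    }
  }
  structure(list(lig_id = lig_id, ccd = lrow$ccd, chain = lrow$chain,
                 cutoff_A = cutoff_A, residues = res),
            class = "pl_binding")
}

#' Extract binding residues for all (non-buffer) ligands of a structure
#'
#' Applies covalent exclusion, then runs [extract_binding_residues()] for
#' every remaining ligand whose component code is not in `exclude_ccd`.
#'
#' @param structure A `pl_structure`.
#' @param cutoff_A Distance cutoff in angstroms.
#' @param exclude_ccd Component codes to skip (buffer media);
#'   see [default_buffer_ccds()].
#' @return List of `pl_binding` annotations.
#' @export
extract_all_binding <- function(structure, cutoff_A = 5,
                                exclude_ccd = default_buffer_ccds()) {
  structure <- exclude_covalent_ligands(structure)
  ligs <- structure$ligands
  ligs <- ligs[!(ligs$ccd %in% exclude_ccd), , drop = FALSE]
  atoms <- structure$atoms
  pol <- atoms$kind == "polymer"
  octree <- if (any(pol)) {
    build_octree(as.matrix(atoms[pol, c("x", "y", "z")]))
  } else NULL
  lapply(ligs$lig_id, function(id) {
    extract_binding_residues(structure, id, cutoff_A, octree = octree)
  })
}

#' Write binding annotations as a tab-separated table
#'
#' Columns: pdb_id, chain, ccd_code, residue_index, author_seq,
#' min_distance_A. This flat table is the package's stand-in for a
#' residue-level binding-site store.
#'
#' @param annotations List of `pl_binding` objects.
#' @param path Output file path.
#' @param pdb_id Identifier recorded in the first column.
#' @return The table, invisibly.
#' @export
write_annotations <- function(annotations, path, pdb_id = "XXXX") {
  tab <- annotations_table(annotations, pdb_id)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @rdname write_annotations
#' @export
annotations_table <- function(annotations, pdb_id = "XXXX") {
  rows <- lapply(annotations, function(a) {
    if (!nrow(a$residues)) return(NULL)
    data.frame(pdb_id = pdb_id, chain = a$residues$chain, ccd_code = a$ccd,
               residue_index = a$residues$res_index,
               author_seq = a$residues$resseq,
               min_distance_A = round(a$residues$min_distance_A, 3),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pdb_id = character(0), chain = character(0),
                      ccd_code = character(0), residue_index = integer(0),
                      author_seq = integer(0), min_distance_A = numeric(0))
  }
  out
}

#' Read an annotation table written by [write_annotations()]
#' @param path Path to the TSV file.
#' @return Data frame with the annotation columns.
#' @export
read_annotations <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(pdb_id = "character", chain = "character",
                                   ccd_code = "character"))
}

#' @export
print.pl_structure <- function(x, ...) {
  cat(sprintf("pl_structure: %d atoms, %d chain(s), %d ligand instance(s), %d covalent link(s)\n",
              nrow(x$atoms), length(x$chains), nrow(x$ligands),
              nrow(x$covalent_links)))
  invisible(x)
}

#' @export
print.pl_binding <- function(x, ...) {
  cat(sprintf("pl_binding: ligand %s (id %d), cutoff %.1f A, %d binding residue(s)\n",
              x$ccd, x$lig_id, x$cutoff_A, nrow(x$residues)))
  invisible(x)
}
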