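# PDB parsing, octree queries, covalent exclusion, binding extraction.

atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                      record = "ATOM", element = "C") {
  sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, chain, resseq, x, y, z, 1.0, 0.0,
          element)
}

test_that("parse_pdb handles minimal, water-only and ligand-bearing files", {
  s <- parse_pdb(atom_line(1, "CA", "ALA", "A", 1, 1, 2, 3))
  expect_length(s$chains, 1)
  expect_equal(nrow(s$chains$A), 1)
  expect_equal(nrow(s$ligands), 0)

  # 3-residue peptide plus one zinc
  lines <- c(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "GLY", "A", 2, 4, 0, 0),
    atom_line(3, "CA", "SER", "A", 3, 8, 0, 0),
    atom_line(4, "ZN", "ZN", "A", 101, 4, 3, 0, record = "HETATM",
              element = "ZN")
  )
  s <- parse_pdb(lines)
  expect_equal(nrow(s$chains$A), 3)
  expect_equal(nrow(s$ligands), 1)
  expect_equal(s$ligands$ccd, "ZN")
  expect_equal(s$ligands$n_atoms, 1L)

  # water-only file: zero ligands, waters discarded entirely
  w <- parse_pdb(c(
    atom_line(1, "O", "HOH", "A", 201, 0, 0, 0, record = "HETATM",
              element = "O"),
    atom_line(2, "O", "HOH", "A", 202, 3, 0, 0, record = "HETATM",
              element = "O")
  ))
  expect_equal(nrow(w$ligands), 0)
  expect_equal(nrow(w$atoms), 0)
})

test_that("parse_pdb rejects malformed and empty input with line numbers", {
  expect_error(parse_pdb("REMARK nothing here"), "no ATOM or HETATM")
  bad <- c(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
           "ATOM      2  CA  ALA A   2      xx.xxx   0.000   0.000")
  expect_error(parse_pdb(bad), "line 2")
})

test_that("parse_pdb keeps first model and first altLoc only", {
  lines <- c(
    "MODEL        1",
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    "ENDMDL",
    "MODEL        2",
    atom_line(2, "CA", "ALA", "A", 1, 99, 99, 99),
    "ENDMDL"
  )
  s <- parse_pdb(lines)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$x, 0)

  # altLoc: two conformers of the same atom, first kept
  al <- c(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
          atom_line(2, "CA", "ALA", "A", 1, 5, 5, 5))
  s2 <- parse_pdb(al)
  expect_equal(nrow(s2$atoms), 1)
  expect_equal(s2$atoms$x, 0)
})

test_that("MSE is folded into the polymer, not a ligand", {
  s <- parse_pdb(atom_line(1, "CA", "MSE", "A", 1, 0, 0, 0,
                           record = "HETATM"))
  expect_equal(nrow(s$ligands), 0)
  expect_equal(nrow(s$chains$A), 1)
})

test_that("octree range queries match brute force", {
  # identity query on a single atom
  t1 <- build_octree(matrix(c(1, 2, 3), 1))
  expect_equal(octree_query(t1, c(1, 2, 3), 0.1), 1L)
  # disjoint query far outside the bounding box
  expect_length(octree_query(t1, c(50, 50, 50), 5), 0)

  set.seed(11)
  coords <- matrix(runif(500 * 3, 0, 50), ncol = 3)
  tree <- build_octree(coords)
  for (q in 1:100) {
    p <- runif(3, 0, 50)
    expect_identical(octree_query(tree, p, 5), brute_force_range(coords, p, 5))
  }
})

test_that("covalent exclusion removes exactly the bonded ligands", {
  # no links: untouched
  fx <- gen_complex(21, 8, c(3))
  s <- parse_pdb(fx$text)
  expect_identical(exclude_covalent_ligands(s)$ligands, s$ligands)

  # ligand bonded to a polymer atom: removed
  fc <- gen_complex(22, 8, c(3), covalent = TRUE)
  sc <- parse_pdb(fc$text)
  expect_equal(nrow(sc$ligands), 1)
  expect_equal(nrow(exclude_covalent_ligands(sc)$ligands), 0)

  # two ligands bonded to each other, neither to the polymer: both removed
  lines <- c(
    atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    atom_line(2, "C1", "AAA", "A", 90, 20, 0, 0, record = "HETATM"),
    atom_line(3, "C1", "BBB", "A", 91, 22, 0, 0, record = "HETATM"),
    sprintf("CONECT%5d%5d", 2L, 3L)
  )
  s3 <- parse_pdb(lines)
  expect_equal(nrow(s3$ligands), 2)
  expect_equal(nrow(exclude_covalent_ligands(s3)$ligands), 0)
})

test_that("LINK records also mark covalent ligands", {
  lines <- c(
    atom_line(1, "SG", "CYS", "A", 1, 0, 0, 0, element = "S"),
    atom_line(2, "C1", "LIG", "A", 90, 2, 0, 0, record = "HETATM"),
    sprintf("LINK        %-4s %3s %1s%4d%1s               %-4s %3s %1s%4d%1s",
            "SG", "CYS", "A", 1L, " ", "C1", "LIG", "A", 90L, " ")
  )
  s <- parse_pdb(lines)
  expect_equal(nrow(s$covalent_links), 1)
  expect_equal(nrow(exclude_covalent_ligands(s)$ligands), 0)
})

test_that("extract_binding_residues finds planted contacts and nothing else", {
  fx <- gen_complex(31, 12, c(3, 7))
  s <- parse_pdb(fx$text)
  ann <- extract_binding_residues(s, 1, 5)
  expect_equal(ann$residues$res_index, c(3L, 7L))
  expect_equal(ann$residues$min_distance_A, rep(4.5, 2), tolerance = 1e-9)
  # matches brute force at the lower printed bound too
  expect_equal(extract_binding_residues(s, 1, 3.5)$residues$res_index,
               brute_force_binding(s, 1, 3.5))

  # a far ligand binds nothing
  far <- parse_pdb(gen_complex(32, 10)$text)
  expect_equal(nrow(extract_binding_residues(far, 1, 5)$residues), 0)

  expect_error(extract_binding_residues(s, 99, 5), "not found")
  expect_error(extract_binding_residues(s, 1, 2), "3.5")
})

test_that("extraction is monotone in the cutoff", {
  for (seed in 1:5) {
    fx <- gen_complex(seed, 10, sample(1:10, 3))
    s <- parse_pdb(fx$text)
    r35 <- extract_binding_residues(s, 1, 3.5)$residues$res_index
    r50 <- extract_binding_residues(s, 1, 5.0)$residues$res_index
    r60 <- extract_binding_residues(s, 1, 6.0)$residues$res_index
    expect_true(all(r35 %in% r50))
    expect_true(all(r50 %in% r60))
  }
})

test_that("parsed coordinates carry the format's 3-decimal precision", {
  fx <- gen_complex(41, 6, c(2))
  s <- parse_pdb(fx$text)
  cb <- s$atoms[s$atoms$name == "CB" & s$atoms$res_index == 2, ]
  lig <- s$atoms[!is.na(s$atoms$lig_id), ]
  d <- sqrt((cb$x - lig$x)^2 + (cb$y - lig$y)^2 + (cb$z - lig$z)^2)
  expect_equal(d, fx$manifest$planted_distance_A, tolerance = 2e-3)
})

test_that("annotation tables round-trip through TSV", {
  fx <- gen_complex(51, 10, c(2, 8))
  s <- parse_pdb(fx$text)
  anns <- extract_all_binding(s, 5, exclude_ccd = character(0))
  tf <- tempfile(fileext = ".tsv")
  tab <- write_annotations(anns, tf, pdb_id = "FIX1")
  back <- read_annotations(tf)
  expect_equal(back$residue_index, tab$residue_index)
  expect_equal(back$ccd_code, tab$ccd_code)
})
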