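pdbqt_line <- function(serial, name, x, y, z, charge, type) {
  sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          serial, name, "UNK", "A", 1L, x, y, z, 1, 0, charge, type)
}

test_that("PDBQT parser reads charges and types from fixed columns", {
  path <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(pdbqt_line(1, "C1", 1.0, 2.0, 3.0, -0.3, "C"),
               pdbqt_line(2, "O1", 4.5, -1.25, 0.0, 0.1, "OA"),
               pdbqt_line(3, "H1", 0.0, 0.0, 9.125, 0.2, "HD"),
               "END"), path)
  p <- parse_pdbqt(path)
  expect_equal(nrow(p$atoms), 3)
  expect_equal(p$atoms$charge, c(-0.3, 0.1, 0.2))
  expect_equal(p$atoms$atom_type, c("C", "OA", "HD"))
  expect_equal(p$atoms$x, c(1.0, 4.5, 0.0))
  expect_equal(p$atoms$z, c(3.0, 0.0, 9.125))
  # order preserved
  expect_equal(p$atoms$serial, 1:3)
})

test_that("empty and malformed inputs raise informative errors", {
  empty <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines("END", empty)
  expect_error(parse_pdbqt(empty), "no atoms")
  expect_error(parse_pdbqt(tempfile()), "not found")
  bad <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines("ATOM      1  C1  UNK A   1        abc     def", bad)
  expect_error(suppressWarnings(parse_pdbqt(bad)), "line 1")
  unknown <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(pdbqt_line(1, "X1", 0, 0, 0, 0, "Xx"), unknown)
  expect_error(parse_pdbqt(unknown), "Xx")
})

test_that("PDB parser defaults charges to zero and types from elements", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "HETATM    2  O   HOH A   2       8.000   8.000   8.000  1.00  0.00           O",
    "END"), path)
  p <- parse_pdb(path)
  expect_equal(nrow(p$atoms), 1)  # water filtered by default
  expect_equal(p$atoms$charge, 0)
  expect_equal(p$atoms$atom_type, "C")
  expect_equal(unname(unlist(p$atoms[1, c("x", "y", "z")])), c(1, 2, 3))
  p2 <- parse_pdb(path, keep_waters = TRUE)
  expect_equal(nrow(p2$atoms), 2)
  expect_equal(p2$atoms$atom_type[2], "OA")
})

test_that("only the first alternate location survives", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1       1.500   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  p <- parse_pdb(path)
  expect_equal(nrow(p$atoms), 2)
  expect_equal(p$atoms$x, c(1.0, 2.0))
})

test_that("PDBQT round trip preserves coordinates and charges to 3 decimals", {
  prot <- random_test_protein(100, seed = 5)
  path <- withr::local_tempfile(fileext = ".pdbqt")
  write_pdbqt(prot, path)
  p2 <- parse_pdbqt(path)
  expect_equal(nrow(p2$atoms), 100)
  expect_lt(max(abs(coords(p2) - coords(prot))), 5e-4 + 1e-12)
  expect_equal(p2$atoms$charge, prot$atoms$charge, tolerance = 1e-12)
  expect_equal(p2$atoms$atom_type, prot$atoms$atom_type)
})

test_that("site_center is the unweighted mean of ligand atom positions", {
  mk <- function(pts) {
    n <- nrow(pts)
    ligand_structure(data.frame(
      serial = seq_len(n), name = "C", element = "C",
      x = pts[, 1], y = pts[, 2], z = pts[, 3], charge = 0,
      vdw_radius = 2, atom_type = "C"))
  }
  expect_equal(site_center(mk(rbind(c(0, 0, 0), c(2, 0, 0)))), c(1, 0, 0))
  expect_equal(site_center(mk(rbind(c(4, -1, 7)))), c(4, -1, 7))
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(site_center(mk(corners)), c(0.25, 0.25, 0.25))
  expect_error(site_center(list(atoms = NULL)), "empty")
})
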