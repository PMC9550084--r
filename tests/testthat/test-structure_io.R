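test_that("a minimal hand-written PDB parses with numbering preserved", {
  st <- load_structure(write_mini_pdb())
  expect_s3_class(st, "fod_structure")
  rt <- unique(st$atoms[, c("chain", "resno", "resid")])
  expect_equal(nrow(rt), 2L)
  expect_equal(rt$resno, c(1L, 2L))
  expect_equal(rt$resid, c("ALA", "GLY"))
  expect_equal(nrow(st$atoms), 4L)
})

test_that("parse and empty-structure errors are informative", {
  bad <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), bad)
  expect_error(load_structure(bad), "parse|empty|atom")
  expect_error(load_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("multi-model files yield model 1 by default, others on request", {
  base <- mini_pdb_lines()[1:4]
  shifted <- vapply(base, function(l) {
    x <- as.numeric(substr(l, 31, 38)) + 50
    paste0(substr(l, 1, 30), sprintf("%8.3f", x), substr(l, 39, nchar(l)))
  }, character(1), USE.NAMES = FALSE)
  path <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", base, "ENDMDL",
               "MODEL     2", shifted, "ENDMDL", "END"), path)
  m1 <- load_structure(path)
  expect_equal(nrow(m1$atoms), 4L)
  expect_equal(m1$atoms$x[1], 0)
  m2 <- load_structure(path, model = 2)
  expect_equal(m2$atoms$x[1], 50)
  avg <- load_structure(path, average_models = TRUE)
  expect_equal(avg$atoms$x[1], 25)
  expect_error(load_structure(path, model = 3), "models")
})

test_that("mmCIF and PDB fixtures of the same residues parse identically", {
  sp <- load_structure(write_mini_pdb(), format = "pdb")
  sc <- load_structure(write_mini_cif(), format = "mmcif")
  cols <- c("type", "elety", "resid", "chain", "resno", "x", "y", "z")
  expect_equal(sp$atoms[, cols], sc$atoms[, cols],
               ignore_attr = TRUE)
  # auto format detection by extension
  sa <- load_structure(write_mini_cif())
  expect_equal(sa$atoms$x, sc$atoms$x)
})

test_that("effective atoms are unweighted per-residue atom means", {
  st <- load_structure(write_mini_pdb())
  ea <- effective_atoms(st)
  expect_equal(ea$n, 2L)
  expect_equal(unname(ea$xyz[1, ]), c(1, 0, 0))   # mean of (0,0,0),(2,0,0)
  expect_equal(unname(ea$xyz[2, ]), c(0, 5, 0))

  # 5-atom residue against an independent per-coordinate summation oracle
  set.seed(42)
  co <- matrix(round(stats::runif(15, -9, 9), 3), ncol = 3)
  lines <- c(vapply(1:5, function(i)
    pdb_atom_line(i, c("N", "CA", "C", "O", "CB")[i], "LEU", "A", 7,
                  co[i, 1], co[i, 2], co[i, 3]),
    character(1)),
    pdb_atom_line(6, "CA", "GLY", "A", 8, 20, 20, 20, elem = "C"),
    "END")
  p5 <- tempfile(fileext = ".pdb")
  writeLines(lines, p5)
  ea5 <- effective_atoms(load_structure(p5))
  oracle <- c(sum(co[, 1]) / 5, sum(co[, 2]) / 5, sum(co[, 3]) / 5)
  expect_equal(unname(ea5$xyz[1, ]), oracle, tolerance = 1e-3)

  # permutation invariance w.r.t. atom order within a residue
  perm <- tempfile(fileext = ".pdb")
  writeLines(c(lines[c(3, 5, 1, 4, 2)], lines[6], "END"), perm)
  eap <- effective_atoms(load_structure(perm))
  expect_equal(eap$xyz[1, ], ea5$xyz[1, ])
})

test_that("unit selection is inclusive in author numbering", {
  syn <- generate_synthetic(synthetic_spec(n = 116, assignment = "shuffled",
                                           seed = 5))
  path <- tempfile(fileext = ".pdb")
  write_effective_pdb(syn$atoms, path)
  st <- load_structure(path)

  all_sel <- select_unit(st, chains = "A")
  expect_equal(nrow(all_sel$residues), 116L)

  term <- select_unit(st, chains = "A", residue_range = c(100, 116))
  expect_equal(nrow(term$residues), 17L)   # inclusive terminal segment

  mid <- select_unit(st, residue_range = c(79, 112))
  expect_equal(nrow(mid$residues), 34L)

  expect_error(select_unit(st, chains = "B"), "unknown chain")
  expect_error(select_unit(st, residue_range = c(100, 300)), "endpoint")
  # count conservation through effective_atoms
  expect_equal(effective_atoms(st, term)$n, 17L)
})

test_that("unresolved residue numbers inside a range are skipped and reported", {
  keep <- c(1:3, 5:8)
  lines <- c(vapply(seq_along(keep), function(i)
    pdb_atom_line(i, "CA", "ALA", "A", keep[i], i * 4, 0, 0, elem = "C"),
    character(1)), "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  st <- load_structure(path)
  expect_message(sel <- select_unit(st, residue_range = c(1, 8)),
                 "unresolved.*4")
  expect_equal(nrow(sel$residues), 7L)
  expect_equal(attr(sel, "skipped"), 4L)
})

test_that("waters and unmapped HETATM are excluded; mapped ones included", {
  lines <- c(mini_pdb_lines()[1:4],
             pdb_atom_line(5, "O", "HOH", "A", 101, 9, 9, 9,
                           record = "HETATM"),
             pdb_atom_line(6, "CA", "MSE", "A", 3, 0, 8, 0, elem = "C",
                           record = "HETATM"),
             "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  st <- load_structure(path)
  ea <- effective_atoms(st)
  expect_equal(ea$n, 2L)                 # ALA + GLY only
  sel <- select_unit(st, residue_mapping = c(MSE = "MET"))
  eam <- effective_atoms(st, sel, residue_mapping = c(MSE = "MET"))
  expect_equal(eam$n, 3L)
  expect_equal(eam$resid[3], "MET")
})

test_that("disulfide detection pairs SG atoms within the threshold", {
  b <- detect_disulfides(load_structure(write_cys_pdb(2.04)))
  expect_equal(nrow(b), 1L)
  expect_equal(b$sg_distance, 2.04, tolerance = 1e-6)
  expect_equal(c(b$frag_start, b$frag_end), c(3, 9))

  far <- detect_disulfides(load_structure(write_cys_pdb(5)))
  expect_equal(nrow(far), 0L)
  # threshold is configurable
  wide <- detect_disulfides(load_structure(write_cys_pdb(5)), threshold = 6)
  expect_equal(nrow(wide), 1L)
  # no cysteines at all
  none <- detect_disulfides(load_structure(write_mini_pdb()))
  expect_equal(nrow(none), 0L)
})

test_that("effective atoms round-trip through a CA-only PDB at 1e-3 A", {
  syn <- generate_synthetic(synthetic_spec(n = 30, assignment = "shuffled",
                                           seed = 11))
  path <- tempfile(fileext = ".pdb")
  write_effective_pdb(syn$atoms, path)
  back <- effective_atoms(load_structure(path))
  expect_equal(back$n, 30L)
  expect_lt(max(abs(back$xyz - syn$atoms$xyz)), 1e-3)
})
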