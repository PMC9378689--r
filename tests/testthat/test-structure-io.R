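test_that("a minimal PDB file parses into chains, residues and atoms", {
  lines <- c(
    "ATOM      1  N   GLY A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   GLY A   1      10.729   6.768  -4.123  1.00  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  m <- read_structure(path)
  expect_s3_class(m, "StructureModel")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(unique(m$atoms$chain), "A")
  expect_equal(unique(m$atoms$resno), 1L)
  expect_setequal(m$atoms$name, c("N", "CA", "C"))
})

test_that("PDB and mmCIF writers round-trip one in-memory model identically", {
  fx <- make_duplex(n_pairs = 5L)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  write_structure(fx$model, pdb, "pdb")
  write_structure(fx$model, cif, "cif")
  m_pdb <- suppressWarnings(read_structure(pdb))
  m_cif <- suppressWarnings(read_structure(cif))
  ref <- fx$model
  ref$atoms <- ref$atoms[order(ref$atoms$chain, ref$atoms$resno,
                               ref$atoms$name), ]
  ref$atoms$serial <- seq_len(nrow(ref$atoms))
  rownames(ref$atoms) <- NULL
  expect_same_atoms(m_pdb, ref, tol = 1e-3)   # PDB fixed width: 3 decimals
  expect_same_atoms(m_cif, ref, tol = 1e-3)
  expect_same_atoms(m_pdb, m_cif, tol = 1e-9)
  # second round trip is exact: fixed-width quantisation happened once
  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m_pdb, pdb2, "pdb")
  expect_same_atoms(suppressWarnings(read_structure(pdb2)), m_pdb, tol = 1e-9)
})

test_that("altloc resolution keeps the highest occupancy, ties to first alphabetically", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB BALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x[m$atoms$name == "CA"], 1.0)  # occ 0.6 wins
  expect_equal(m$atoms$x[m$atoms$name == "CB"], 3.0)  # tie: altloc A wins
  # idempotent and deterministic
  m2 <- read_structure(path)
  expect_identical(m$atoms, m2$atoms)
})

test_that("waters are dropped by default and metal ions flagged", {
  xyz <- matrix(seq_len(9), 3L, 3L)
  rows <- data.frame(serial = 1:3, name = c("CA", "ZN", "O"),
                     elem = c("C", "ZN", "O"),
                     resid = c("ALA", "ZN", "HOH"), chain = "A",
                     resno = 1:3, insert = "", x = xyz[, 1], y = xyz[, 2],
                     z = xyz[, 3], occ = 1, alt = "",
                     het = c(FALSE, TRUE, TRUE))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(structure_model(rows, id = "ion"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(sum(m$atoms$is_ion), 1L)
  expect_equal(m$atoms$resid[m$atoms$is_ion], "ZN")
  m_w <- read_structure(path, keep_waters = TRUE)
  expect_equal(nrow(m_w$atoms), 3L)
})

test_that("selection semantics: ranges, atom names, set union, monotonicity", {
  xyz <- cbind(seq_len(10), 0, 0)
  m <- mk_model(rep(c("CA", "CB"), 5L), "C", "ALA", "A",
                rep(1:5, each = 2L), xyz)
  expect_equal(nrow(select_atoms(m, selection("A", c(1, 3), atoms = "CA"))), 3L)
  # overlapping ranges have set semantics
  both <- select_atoms(m, selection("A", list(c(1, 3), c(2, 5))))
  expect_equal(nrow(both), 10L)
  expect_false(any(duplicated(paste(both$resno, both$name))))
  # enlarging a range never removes atoms
  for (hi in 1:5) {
    small <- select_atoms(m, selection("A", c(1, hi)))
    big <- select_atoms(m, selection("A", c(1, min(hi + 1L, 5L))))
    expect_true(all(paste(small$resno, small$name) %in%
                      paste(big$resno, big$name)))
  }
  expect_error(select_atoms(m, selection("Z")), "zero atoms")
  expect_error(selection("A", c(5, 1)), "start exceeds end")
  # string syntax
  expect_equal(nrow(select_atoms(m, "A:2-4:CB")), 3L)
})

test_that("domain configs load, validate disjointness and resolve on structures", {
  ds <- load_domain_config()
  expect_true(all(c("core", "clamp", "shelf", "jaw", "SI3",
                    "betaprime_cterm") %in% names(ds$domains)))
  # overlap between swivel members is rejected
  expect_error(domain_set(list(core = "C:1-10", clamp = "D:1-100",
                               shelf = "D:90-200", jaw = "D:300-400",
                               SI3 = "D:410-500", betaprime_cterm = "D:510-600")),
               "overlap")
  expect_error(domain_set(list(core = "C:1-10", clamp = "D:1-100")),
               "mandatory")
  # a config naming an absent chain fails resolution with the chain named
  fx <- make_two_module_model(seed = 1L)
  ds_bad <- domain_set(list(core = "Q:1-300", clamp = "C:1001-1040",
                            shelf = "C:1041-1080", jaw = "C:1081-1120",
                            SI3 = "C:1121-1160", betaprime_cterm = "C:1161-1200"))
  expect_error(swivel_angle(fx$reference, fx$target, ds_bad), "Q")
})

test_that("unparseable files and empty models raise errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a coordinate file", path)
  expect_error(suppressWarnings(read_structure(path)))
  expect_error(read_structure(file.path(tempdir(), "absent.pdb")), "not found")
})
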