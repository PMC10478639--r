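test_that("reading a hand-written PDB fragment captures residue confidences", {
  m <- read_model(pdb_fragment, format = "pdb")
  res <- residues(m)
  expect_equal(nrow(res), 2)
  expect_equal(res$raw_confidence, c(88, 42))
  expect_equal(res$resid, c("ALA", "GLY"))
  expect_equal(res$resno, c(1L, 2L))
  # auto-detection picks PDB for non-mmCIF text
  expect_equal(residues(read_model(pdb_fragment))$raw_confidence, c(88, 42))
})

test_that("PDB write/read round trip preserves identity and column precision", {
  fx <- generate_model(synthetic_spec(seed = 21))
  m <- fx$model
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model(m, f, format = "pdb")
  m2 <- read_model(f)
  expect_identical(residues(m2)[, c("chain", "resno", "icode", "resid")],
                   residues(m)[, c("chain", "resno", "icode", "resid")])
  expect_identical(m2$atom, m$atom)
  expect_lt(max(abs(m2$x - m$x), abs(m2$y - m$y), abs(m2$z - m$z)), 1e-3)
  expect_lt(max(abs(m2$b - m$b)), 1e-2)
})

test_that("the same structure as PDB and mmCIF parses identically", {
  fx <- generate_model(synthetic_spec(seed = 22))
  m <- fx$model
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  write_model(m, fp, format = "pdb")
  write_model(m, fc, format = "mmcif")
  mp <- read_model(fp)
  mc <- read_model(fc)   # auto-detected from data_ header
  expect_identical(residues(mp)[, c("chain", "resno", "icode", "resid")],
                   residues(mc)[, c("chain", "resno", "icode", "resid")])
  expect_equal(residues(mc)$raw_confidence, residues(mp)$raw_confidence,
               tolerance = 1e-8)
  expect_lt(max(abs(mc$x - mp$x)), 1e-6)
})

test_that("PDB numeric formatting follows the fixed-width convention", {
  m <- line_model(3, b = 59.2176)
  lines <- write_model(m, format = "pdb")
  expect_true(any(grepl(" 59.22", lines, fixed = TRUE)))
})

test_that("write_model rejects empty and unrepresentable models", {
  expect_error(predicted_model(tibble::tibble(
    atom = character(), resid = character(), chain = character(),
    resno = integer(), x = numeric(), y = numeric(), z = numeric(),
    occ = numeric(), b = numeric())), "no atoms")
  wide <- ca_model(matrix(c(123456.0, 0, 0), 1, 3), b = 50)
  expect_error(write_model(wide, format = "pdb"), "unrepresentable in PDB")
  # the same model is fine as mmCIF
  expect_no_error(write_model(wide, format = "mmcif"))
})

test_that("PAE JSON dialects all parse to the same matrix", {
  p <- pae_matrix(matrix(c(0, 4, 7, 4.5, 0, 2, 6.5, 2.2, 0), 3, 3,
                         byrow = TRUE), max_pae = 31.75)
  parsed <- lapply(c("afdb_nested", "afdb_flat", "pae"), function(dl) {
    read_pae_json(write_pae_json(p, dialect = dl))
  })
  for (q in parsed) {
    expect_equal(unclass(q)[, ], unclass(p)[, ], tolerance = 1e-12)
  }
  # nested dialect direct read
  q <- read_pae_json('{"pae": [[0, 4], [4, 0]]}')
  expect_equal(dim(q), c(2L, 2L))
  expect_equal(sort(unique(as.vector(q))), c(0, 4))
})

test_that("malformed PAE inputs are rejected with specific errors", {
  expect_error(read_pae_json('{"pae": [[0, 4, 1], [4, 0, 2]]}'),
               "inconsistent PAE")
  expect_error(read_pae_json('{"pae": [[0, -4], [4, 0]]}'), "invalid PAE value")
  expect_error(read_pae_json('{"something": [[0]]}'), "unknown PAE dialect")
  # flat dialect must cover every index pair
  expect_error(read_pae_json(
    '[{"residue1": [1, 1, 2], "residue2": [1, 2, 1], "distance": [0, 3, 3]}]'),
    "inconsistent PAE")
})

test_that("AFDB URLs follow the documented naming convention", {
  u <- afdb_entry_urls("P69905", 4)
  expect_true(endsWith(u$model_pdb, "AF-P69905-F1-model_v4.pdb"))
  expect_true(endsWith(u$model_cif, "AF-P69905-F1-model_v4.cif"))
  expect_true(endsWith(u$pae_json, "AF-P69905-F1-predicted_aligned_error_v4.json"))
  u3 <- afdb_entry_urls("P69905", 3)
  expect_equal(gsub("_v3", "_v9", u3$model_pdb),
               gsub("_v4", "_v9", u$model_pdb))
  expect_error(afdb_entry_urls("", 4), "invalid accession")
  expect_error(afdb_entry_urls("not-an-acc", 4), "invalid accession")
})

test_that("parsing drops non-polymer records and keeps file order", {
  txt <- c(
    "ATOM      1  CA  ALA A   5      1.000   0.000   0.000  1.00 90.00           C",
    "ATOM      2  CA BGLY A   6      4.800   0.000   0.000  1.00 80.00           C",
    "ATOM      3  CA AGLY A   6      4.800   0.000   0.000  1.00 80.00           C",
    "HETATM    4  O   HOH A 101      9.000   0.000   0.000  1.00 30.00           O",
    "ATOM      5  CA  SER A   4      8.600   0.000   0.000  1.00 70.00           C",
    "END"
  )
  m <- read_model(txt, format = "pdb")
  res <- residues(m)
  # altloc B dropped, water dropped, file order (5, 6, 4) kept
  expect_equal(res$resno, c(5L, 6L, 4L))
  expect_equal(res$raw_confidence, c(90, 80, 70))
  expect_error(read_model("END", format = "pdb"), "no atoms")
})
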