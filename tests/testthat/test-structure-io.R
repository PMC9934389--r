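# structure_io: PDB parsing, hydrogen bonds, helix annotation

minimal_pdb <- function() {
  # two alanines, hand-written records (5 heavy atoms each)
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.400   2.400   0.300  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.900  -0.800  -1.200  1.00  0.00           C",
    "ATOM      6  N   ALA A   2       3.300   1.500  -0.200  1.00  0.00           N",
    "ATOM      7  CA  ALA A   2       4.000   2.800  -0.300  1.00  0.00           C",
    "ATOM      8  C   ALA A   2       5.400   2.600  -0.800  1.00  0.00           C",
    "ATOM      9  O   ALA A   2       5.800   1.500  -1.200  1.00  0.00           O",
    "ATOM     10  CB  ALA A   2       4.100   3.500   1.100  1.00  0.00           C")
}

test_that("minimal hand-written PDB parses to the expected inventory", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb(), f)
  s <- read_structure(f)
  expect_s3_class(s, "ks_structure")
  expect_equal(length(unique(s$residues$chain)), 1L)
  expect_equal(nrow(s$residues), 2L)
  expect_equal(nrow(s$atoms), 10L)
  expect_true(all(s$residues$complete))
  expect_equal(s$residues$aa1, c("A", "A"))
})

test_that("hydrogens, waters, HETATM and duplicate altlocs are filtered", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    minimal_pdb(),
    "ATOM     11  HB1 ALA A   2       4.000   4.000   1.500  1.00  0.00           H",
    "HETATM   12  C1  LIG A 101       9.000   9.000   9.000  1.00  0.00           C",
    "ATOM     13  O   HOH A 201       8.000   8.000   8.000  1.00  0.00           O",
    "ATOM     14  CB ASER A   3       6.000   5.000   0.000  0.40  0.00           C",
    "ATOM     15  CB BSER A   3       6.300   5.100   0.100  0.60  0.00           C"),
    f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 11L)  # 10 + one SER CB
  ser <- s$atoms[s$atoms$resname == "SER", ]
  expect_equal(ser$altloc, "B")  # higher occupancy wins
  expect_false(any(s$atoms$resname %in% c("HOH", "LIG")))
  # incomplete SER (backbone missing) flagged
  expect_false(s$residues$complete[s$residues$resname == "SER"])
})

test_that("multi-model files honour model selection and report availability", {
  f <- withr::local_tempfile(fileext = ".pdb")
  shift <- function(lines, dz) {
    z <- as.numeric(substr(lines, 47, 54)) + dz
    paste0(substr(lines, 1, 46), sprintf("%8.3f", z), substr(lines, 55, 80))
  }
  writeLines(c("MODEL        1", minimal_pdb(), "ENDMDL",
               "MODEL        2", shift(minimal_pdb(), 5), "ENDMDL"), f)
  s1 <- read_structure(f)            # default: first model
  s2 <- read_structure(f, model_index = 2)
  expect_equal(s2$atoms$z, s1$atoms$z + 5)
  expect_error(read_structure(f, model_index = 3), "available models: 1, 2")
})

test_that("write_pdb round-trips coordinates at format precision", {
  h <- make_ideal_helix("AVGLIAAYAALV")  # mixed composition incl. Gly/Leu/Ile/Val
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), nrow(h$atoms))
  expect_equal(s$residues$resname, h$residues$resname)
  expect_equal(s$atoms$atom, h$atoms$atom)
  expect_equal(s$atoms$x, h$atoms$x, tolerance = 1e-3)
  expect_equal(s$atoms$z, h$atoms$z, tolerance = 1e-3)
  # idempotence: second round trip is exact
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f2)
  s2 <- read_structure(f2)
  expect_identical(s$atoms, s2$atoms)
  # TER records separate chains in multi-chain output
  fx <- two_helix()$fx$structure
  f3 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx, f3)
  expect_equal(sum(startsWith(readLines(f3), "TER")), 2L)
  s3 <- read_structure(f3)
  expect_equal(s3$residues$chain, fx$residues$chain)
})

test_that("writing an empty structure errors", {
  h <- make_ideal_helix("AA")
  h$atoms <- h$atoms[0, ]
  expect_error(write_pdb(h, tempfile()), "empty")
})

test_that("ideal 12-mer helix has every i to i+4 backbone hydrogen bond", {
  w <- helix12()
  i4 <- w$hb[w$hb$donor - w$hb$acceptor == 4L, ]
  expect_setequal(i4$acceptor, 1:8)
  expect_true(all(i4$dist <= 3.5))
})

test_that("residues far apart or in extended geometry yield no helical bonds", {
  ext <- make_extended_chain(10)
  hb <- detect_backbone_hbonds(ext)
  expect_false(any(hb$donor - hb$acceptor == 4L))
  expect_equal(nrow(assign_helices(ext, hb)), 0L)
  # two residues 50 A apart: no bonds at all
  h1 <- make_ideal_helix("A")$atoms
  h2 <- make_ideal_helix("A", origin = c(50, 0, 0))$atoms
  h2$resseq <- 2L
  s <- knobsocket:::new_structure(rbind(h1, h2))
  expect_equal(nrow(detect_backbone_hbonds(s)), 0L)
})

test_that("helix annotation finds one full-span helix on the ideal 12-mer", {
  w <- helix12()
  expect_equal(nrow(w$hel), 1L)
  expect_equal(w$hel$start_ord, 1L)
  expect_equal(w$hel$end_ord, 12L)
  expect_equal(w$hel$label, "H1")
})

test_that("helix annotation is invariant under rigid-body transforms", {
  w <- helix12()
  for (seed in 1:3) {
    s2 <- transform_structure(w$s, random_rigid(seed))
    hb2 <- detect_backbone_hbonds(s2)
    expect_equal(assign_helices(s2, hb2), w$hel)
  }
})

test_that("single-residue and all-complete invariants hold", {
  one <- make_ideal_helix("A")
  expect_equal(nrow(one$residues), 1L)
  hb <- detect_backbone_hbonds(one)
  expect_equal(nrow(assign_helices(one, hb)), 0L)
  g <- groove()
  hel <- g$res$helices
  res <- g$res$structure$residues
  for (k in seq_len(nrow(hel))) {
    span <- res$chain == hel$chain[k] & res$chain_ord >= hel$start_ord[k] &
      res$chain_ord <= hel$end_ord[k]
    expect_true(all(res$complete[span]))
  }
})

test_that("structure summary labels helices and flanking coils per chain", {
  g <- groove()
  sm <- structure_summary(g$res$structure, g$res$helices)
  a <- sm[sm$chain == "A", ]
  expect_equal(a$label, c("H1", "H2", "H3"))
  expect_equal(sm$label[sm$chain == "B"], "H1")
  # coil labels appear when a chain has non-helical ends
  ext <- make_extended_chain(6)
  sme <- structure_summary(ext, assign_helices(ext, detect_backbone_hbonds(ext)))
  expect_equal(sme$label, "C0-")
})
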