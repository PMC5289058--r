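test_that("PDB write/read round-trip preserves atoms and coordinates", {
  pa <- make_mini_domains()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(pa, f)
  sys <- read_structure(f)
  expect_equal(nrow(sys$atoms), nrow(pa$atoms))
  asm <- extract_modeling_units(sys, list(VA = list(chain = "A"),
                                          VB = list(chain = "B")))
  expect_equal(nrow(asm$atoms), nrow(pa$atoms))
  expect_lt(max(abs(assembly_xyz(asm) - assembly_xyz(pa))), 1e-3)
  # chains are emitted in unit order
  expect_equal(unique(sys$atoms$chain), c("A", "B"))
})

test_that("reading rejects files without protein content", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  expect_error(read_structure(f), "no protein")
  expect_error(read_structure(tempfile()), "cannot read")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.600   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       1.800   2.500   0.000  1.00  0.00           O",
    "END"), f)
  sys <- read_structure(f)
  ca <- sys$atoms[sys$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 1.6)
})

test_that("unit extraction keeps mapped residues untouched and errors on bad maps", {
  pt <- make_mini_ternary()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(pt, f)
  sys <- read_structure(f)
  map <- list(VA = list(chain = "A"), VB = list(chain = "B"),
              PMHC = list(list(chain = "P", peptide = TRUE),
                          list(chain = "M"), list(chain = "N")))
  asm <- extract_modeling_units(sys, map)
  expect_setequal(unit_labels(asm), c("VA", "VB", "PMHC"))
  expect_equal(asm$meta$peptide_chain, "P")
  # retained coordinates are exactly the file values (no re-derivation)
  va_sys <- sys$atoms[sys$atoms$chain == "A", c("x", "y", "z")]
  va_asm <- asm$atoms[asm$atoms$unit == "VA", c("x", "y", "z")]
  expect_identical(unname(as.matrix(va_asm)), unname(as.matrix(va_sys)))
  # TCR-only map gives a 2-unit assembly
  asm2 <- extract_modeling_units(sys, map[c("VA", "VB")])
  expect_setequal(unit_labels(asm2), c("VA", "VB"))
  expect_error(extract_modeling_units(sys, list(VA = list(chain = "Z"),
                                                VB = list(chain = "B"))),
               "mapping error")
  expect_error(extract_modeling_units(sys, list(VA = list(chain = "A"))),
               "mapping error")
})

test_that("unit-map files parse into extraction maps", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# example", "VA D 1 110", "VB E 1 115",
               "PMHC A 1 180", "PMHC C 1 9 peptide"), f)
  m <- read_unit_map(f)
  expect_setequal(names(m), c("VA", "VB", "PMHC"))
  expect_equal(m$VA[[1]]$chain, "D")
  expect_equal(m$VA[[1]]$resno, c(1L, 110L))
  expect_true(m$PMHC[[2]]$peptide)
  expect_false(m$PMHC[[1]]$peptide)
})

test_that("amide hydrogen placement is planar, idempotent and heavy-atom safe", {
  pa <- make_mini_domains()
  rows <- tcrdom:::residue_rows(pa, "A", 3L)
  res <- pa$atoms[rows, ]
  heavy_before <- res[res$elesy != "H", c("elety", "x", "y", "z")]
  pa2 <- place_amide_hydrogens(pa, "A", 3L)
  rows2 <- tcrdom:::residue_rows(pa2, "A", 3L)
  res2 <- pa2$atoms[rows2, ]
  heavy_after <- res2[res2$elesy != "H", c("elety", "x", "y", "z")]
  expect_identical(heavy_before[order(heavy_before$elety), ],
                   heavy_after[order(heavy_after$elety), ],
                   ignore_attr = TRUE)
  p <- function(df, nm) as.numeric(df[df$elety == nm, c("x", "y", "z")])
  # planarity: hydrogens lie in the Cdelta/Oeps1/Neps2 plane
  C <- p(res2, "CD"); O <- p(res2, "OE1"); N <- p(res2, "NE2")
  nrm <- tcrdom:::crossprod3(O - C, N - C)
  nrm <- nrm / sqrt(sum(nrm^2))
  for (h in c("HE21", "HE22")) {
    expect_lt(abs(sum((p(res2, h) - N) * nrm)), 1e-6)
    expect_equal(sqrt(sum((p(res2, h) - N)^2)), 1.01, tolerance = 1e-9)
  }
  # idempotence: re-placement reproduces identical hydrogen coordinates
  pa3 <- place_amide_hydrogens(pa2, "A", 3L)
  res3 <- pa3$atoms[tcrdom:::residue_rows(pa3, "A", 3L), ]
  for (h in c("HE21", "HE22")) {
    expect_equal(p(res3, h), p(res2, h), tolerance = 1e-12)
  }
  # missing carboxamide heavy atom
  broken <- pa
  broken$atoms <- broken$atoms[!(broken$atoms$chain == "A" &
                                   broken$atoms$resno == 3L &
                                   broken$atoms$elety == "NE2"), ]
  expect_error(place_amide_hydrogens(broken, "A", 3L), "incomplete residue")
  # non-carboxamide residue
  expect_error(place_amide_hydrogens(pa, "A", 1L), "unsupported residue")
})

test_that("writing an empty assembly fails", {
  pa <- make_mini_domains()
  empty <- pa
  empty$atoms <- empty$atoms[0, ]
  expect_error(write_structure(empty, tempfile(fileext = ".pdb")), "empty")
})
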