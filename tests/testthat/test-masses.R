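test_that("modification masses match the annotated adduct shifts", {
  mods <- standardModifications()
  pg <- modificationMass(mods$phosphogluconoyl)
  expect_equal(round(pg[["monoisotopic"]], 3), 258.014)
  expect_equal(round(pg[["monoisotopic"]]), 258)
  expect_equal(round(pg[["average"]]), 258)
  ph <- modificationMass(mods$phospho)
  expect_equal(round(ph[["monoisotopic"]], 3), 79.966)
  expect_equal(round(ph[["monoisotopic"]]), 80)
  expect_error(ModificationSpec("empty", integer(0)), "non-empty")
  expect_error(ModificationSpec("zero", c(C = 0, H = 0)), "all zero")
  expect_error(
    modificationMass(ModificationSpec("odd", c(Xx = 1))), "unknown element")
})

test_that("peptide monoisotopic masses are additive over residues and mods", {
  # two glycines plus water, hand-summed
  expect_equal(peptideMonoisotopicMass("GG"), 2 * 57.02146 + 18.0105646,
               tolerance = 1e-6)
  pg <- standardModifications()$phosphogluconoyl
  plain <- peptideMonoisotopicMass("SNPYVKTYLLPD")
  modified <- peptideMonoisotopicMass(
    ModifiedPeptide("SNPYVkTYLLPD", mods = list(k = pg)))
  expect_equal(modified - plain, modificationMass(pg)[["monoisotopic"]],
               tolerance = 1e-9)
  expect_error(peptideMonoisotopicMass("GXG"), "unknown residue")
  expect_error(peptideMonoisotopicMass(""), "empty")
  # modifications must target a matching residue
  expect_error(ModifiedPeptide("GaGA", mods = list(a = pg)), "not a target")
})

test_that("fragment ladders have n-1 ions per series with correct masses", {
  lad <- fragmentLadder("GG")
  expect_equal(nrow(lad), 2)
  b1 <- lad$mz[lad$ion == "b1"]
  expect_equal(b1, 57.02146 + 1.00727646, tolerance = 1e-5)
  y1 <- lad$mz[lad$ion == "y1"]
  expect_equal(y1, 57.02146 + 18.0105646 + 1.00727646, tolerance = 1e-5)
  # a di-glycine b2 fragment (from a longer peptide), hand-summed
  ladGGA <- fragmentLadder("GGA")
  expect_equal(ladGGA$mz[ladGGA$ion == "b2"], 2 * 57.02146 + 1.00727646,
               tolerance = 1e-4)
  lad12 <- fragmentLadder("SNPYVKTYLLPD")
  expect_equal(sum(lad12$series == "b"), 11)
  expect_equal(sum(lad12$series == "y"), 11)
  expect_error(fragmentLadder("G"), "at least 2")
  expect_error(fragmentLadder("GG", charge = 2), "singly-charged")
})

test_that("site modifications shift exactly the fragments containing the site", {
  pg <- standardModifications()$phosphogluconoyl
  shift <- modificationMass(pg)[["monoisotopic"]]
  plain <- fragmentLadder("SNPYVKTYLLPD")
  modded <- fragmentLadder(ModifiedPeptide("SNPYVkTYLLPD", list(k = pg)))
  for (i in 1:11) {
    bDelta <- modded$mz[modded$ion == paste0("b", i)] -
      plain$mz[plain$ion == paste0("b", i)]
    yDelta <- modded$mz[modded$ion == paste0("y", i)] -
      plain$mz[plain$ion == paste0("y", i)]
    # modification at position 6 of 12: b6..b11 shifted, y7..y11 shifted
    expect_equal(bDelta, if (i >= 6) shift else 0, tolerance = 1e-9)
    expect_equal(yDelta, if (i >= 7) shift else 0, tolerance = 1e-9)
  }
})

test_that("b/y ladders conserve the precursor mass at every cleavage", {
  pg <- standardModifications()$phosphogluconoyl
  peptides <- list(
    ModifiedPeptide("SNPYVkTYLLPD", list(k = pg)),
    ModifiedPeptide("ACDEFGHIKLMNPQRSTVWY"),
    ModifiedPeptide("KAkA", list(k = pg)))
  proton <- 1.00727646
  for (pep in peptides) {
    total <- peptideMonoisotopicMass(pep)
    lad <- fragmentLadder(pep)
    n <- nchar(pep@sequence)
    for (k in seq_len(n - 1)) {
      bk <- lad$mz[lad$ion == paste0("b", k)]
      ynk <- lad$mz[lad$ion == paste0("y", n - k)]
      expect_equal(bk + ynk, total + 2 * proton, tolerance = 1e-6)
    }
  }
})

test_that("ppm matching is symmetric about the theoretical mass", {
  expect_true(withinPpm(1000, 1000 + 1000 * 20e-6, 20))
  expect_true(withinPpm(1000, 1000 - 1000 * 20e-6, 20))
  expect_false(withinPpm(1000, 1000 + 1000 * 21e-6, 20))
  expect_false(withinPpm(1000, 1000 - 1000 * 21e-6, 20))
})

test_that("intact mass shifts rank the correct modification first", {
  mods <- standardModifications()
  hit258 <- matchIntactMassShift(258, mods)
  expect_equal(hit258$modifications[1], "phosphogluconoyl")
  expect_lt(hit258$error[1], 0.1)
  hit80 <- matchIntactMassShift(80, mods)
  expect_equal(hit80$modifications[1], "phospho")
  none <- matchIntactMassShift(999, mods)
  expect_equal(nrow(none), 0)
  # pair sums are considered: two phosphogluconoyl adducts
  hit516 <- matchIntactMassShift(516, mods)
  expect_equal(hit516$modifications[1],
               "phosphogluconoyl + phosphogluconoyl")
})

test_that("a single 258 Da shift makes cluster lysine sites mutually exclusive", {
  pg <- standardModifications()$phosphogluconoyl
  res <- enumerateSiteAssignments(258, pg, c("K398", "K412"))
  expect_equal(res$nCopies, 1L)
  expect_equal(res$assignments, list("K398", "K412"))
  res2 <- enumerateSiteAssignments(516, pg, c("K398", "K412"))
  expect_equal(res2$nCopies, 2L)
  expect_equal(res2$assignments, list(c("K398", "K412")))
  resNone <- enumerateSiteAssignments(100, pg, c("K398", "K412"))
  expect_equal(resNone$nCopies, 0L)
})
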