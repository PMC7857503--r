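# small hand-built bilayer: two leaflets of phosphorus atoms and a protein
miniBilayer <- function(pUpper = c(19, 21), pLower = c(-19, -21),
                        proteinZ = 45) {
  nP <- length(pUpper) + length(pLower)
  lip <- data.frame(
    atom = "P", element = "P", resname = "POPC",
    resno = seq_len(nP), segid = "MEMB",
    x = seq_len(nP) * 8, y = 0, z = c(pUpper, pLower), mass = 30.974)
  prot <- data.frame(
    atom = "CA", element = "C", resname = "GLY", resno = 1L,
    segid = "PROA", x = 0, y = 0, z = proteinZ, mass = 12.011)
  MembraneFrame(rbind(lip, prot))
}

test_that("phosphate plane is the leaflet mean and leaflets resolve correctly", {
  fr <- miniBilayer(pUpper = c(0, 0), pLower = c(-40, -40), proteinZ = 20)
  expect_equal(phosphatePlaneZ(fr, "upper"), 0)
  fr2 <- miniBilayer(pUpper = c(19, 21), pLower = c(-19, -21), proteinZ = 45)
  expect_equal(phosphatePlaneZ(fr2, "upper"), 20)
  expect_equal(phosphatePlaneZ(fr2, "lower"), -20)
  expect_equal(phosphatePlaneZ(fr2, "protein_facing"), 20)
  # protein below the bilayer flips the protein-facing leaflet
  fr3 <- miniBilayer(proteinZ = -45)
  expect_equal(phosphatePlaneZ(fr3, "protein_facing"), -20)
  noP <- caFrame(1, c(0, 0, 0))
  expect_error(phosphatePlaneZ(noP), "missing selection")
})

test_that("protein COM height matches point masses and a brute-force oracle", {
  fr <- miniBilayer(proteinZ = 45)
  expect_equal(proteinComHeight(fr), 25)
  expect_equal(proteinComHeight(fr, planeZ = 20), 25)
  # rigid z-translation leaves the height unchanged
  a <- atoms(fr); a$z <- a$z + 13.7
  expect_equal(proteinComHeight(MembraneFrame(a)), 25, tolerance = 1e-12)
  # 1000-atom random protein against the explicit mass-weighted sum
  set.seed(42)
  n <- 1000
  prot <- data.frame(
    atom = "CA", element = sample(c("C", "N", "O", "S"), n, TRUE),
    resname = "ALA", resno = seq_len(n), segid = "PROA",
    x = rnorm(n), y = rnorm(n), z = rnorm(n, 30, 5))
  prot$mass <- elementMass(prot$element)
  fr2 <- MembraneFrame(prot)
  oracle <- sum(prot$mass * prot$z) / sum(prot$mass)
  expect_equal(proteinCenterOfMass(fr2)[3], oracle, tolerance = 1e-9)
})

test_that("residue depth follows the sign convention and is translation invariant", {
  lip <- data.frame(atom = "P", element = "P", resname = "POPC",
                    resno = 1:2, segid = "MEMB", x = c(0, 8), y = 0,
                    z = 20, mass = 30.974)
  prot <- data.frame(
    atom = c("CA", "CZ"), element = "C", resname = "PHE", resno = 452L,
    segid = "PROA", x = 0, y = 0, z = c(20, 17.5), mass = 12.011)
  fr <- MembraneFrame(rbind(lip, prot))
  expect_equal(residueDepth(fr, 452, planeZ = 20), 0)
  expect_equal(residueDepth(fr, 452, "named_atom", atomName = "CZ",
                            planeZ = 20), -2.5)
  a <- atoms(fr); a$z <- a$z + 100
  fr2 <- MembraneFrame(a)
  expect_equal(residueDepth(fr2, 452, planeZ = 120), 0, tolerance = 1e-12)
  expect_error(residueDepth(fr, 452, "named_atom", atomName = "NZ",
                            planeZ = 20), "missing atom")
})

test_that("loop tips are C-alpha centroids, order independent", {
  fr <- caFrame(1:3, rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)))
  loop <- LoopDefinition("test", 1:3)
  expect_equal(loopTipPosition(fr, loop), c(3, 0, 0))
  # permuting residue numbering leaves the tip unchanged
  fr2 <- caFrame(c(3, 1, 2), rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)))
  expect_equal(loopTipPosition(fr2, loop), c(3, 0, 0))
  # random coordinates against the explicit mean
  set.seed(7)
  xyz <- matrix(rnorm(9), 3)
  fr3 <- caFrame(1:3, xyz)
  expect_equal(loopTipPosition(fr3, loop), colMeans(xyz), tolerance = 1e-12)
  expect_error(loopTipPosition(caFrame(1:2, matrix(rnorm(6), 2)), loop),
               "missing atom")
})

test_that("interloop angles match constructed geometries", {
  # COM at origin (single atom), orthogonal tips
  xyz <- rbind(c(0, 0, 0),                         # residue 10: the COM
               c(10, 0, 0), c(10, 0, 0), c(10, 0, 0),
               c(0, 10, 0), c(0, 10, 0), c(0, 10, 0))
  # place tip triplets exactly (identical members keep the centroid exact)
  fr <- MembraneFrame(data.frame(
    atom = "CA", element = "C", resname = "GLY",
    resno = c(10L, 1L, 2L, 3L, 4L, 5L, 6L), segid = "PROA",
    x = xyz[, 1] + c(0, -0.1, 0, 0.1, -0.1, 0, 0.1),
    y = xyz[, 2], z = xyz[, 3], mass = 12.011))
  loopA <- LoopDefinition("a", 1:3)
  loopB <- LoopDefinition("b", 4:6)
  # the COM includes the tip atoms; verify against a direct computation
  com <- proteinCenterOfMass(fr)
  va <- c(10, 0, 0) - com; vb <- c(0, 10, 0) - com
  expected <- acos(sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))) * 180 / pi
  expect_equal(interloopAngle(fr, loopA, loopB), expected, tolerance = 1e-9)
  # collinear opposite tips through a central dominant mass: 180 degrees
  heavy <- data.frame(
    atom = "CA", element = "C", resname = "GLY",
    resno = c(1L, 2L, 3L, 4L, 5L, 6L), segid = "PROA",
    x = c(-10, -10, -10, 10, 10, 10), y = 0, z = 0, mass = 12.011)
  fr2 <- MembraneFrame(heavy)  # COM exactly between the two tips
  expect_equal(interloopAngle(fr2, loopA, loopB), 180)
})

test_that("geometric metrics are invariant under random rigid transforms", {
  gen <- buildMembraneProteinFrames(seed = 9, nFrames = 2)
  fr <- frames(gen$trajectory)[[1]]
  loops <- c2aLoopDefinitions()
  # strip the box so distances are plain Euclidean under rotation
  frNoBox <- MembraneFrame(atoms(fr))
  angle0 <- interloopAngle(frNoBox, loops[["beta2-beta3"]],
                           loops[["beta6-beta7"]])
  contacts0 <- lipidContacts(frNoBox)
  for (s in 1:5) {
    rigid <- randomRigid(s)
    frT <- applyRigidToFrame(frNoBox, rigid)
    expect_equal(interloopAngle(frT, loops[["beta2-beta3"]],
                                loops[["beta6-beta7"]]),
                 angle0, tolerance = 1e-6)
    expect_identical(lipidContacts(frT), contacts0)
  }
  # pure z-translation also preserves plane-referenced quantities
  a <- atoms(fr); a$z <- a$z + 31
  frZ <- MembraneFrame(a, box = fr@box)
  expect_equal(proteinComHeight(frZ), proteinComHeight(fr),
               tolerance = 1e-9)
})

test_that("contact counting respects the cutoff boundary and binarization", {
  mkFrame <- function(dist) {
    lip <- data.frame(atom = c("P", "O13", "O14"), element = c("P", "O", "O"),
                      resname = "POPS", resno = 1L, segid = "MEMB",
                      x = c(0, 0, 0), y = 0, z = c(0, -0.5, -1), mass = 1)
    prot <- data.frame(atom = c("CA", "NZ"), element = c("C", "N"),
                       resname = "LYS", resno = 398L, segid = "PROA",
                       x = 0, y = 0, z = c(dist + 1.5, dist), mass = 12)
    MembraneFrame(rbind(lip, prot))
  }
  # anchor 4.9 A above the nearest headgroup atom: one contact
  expect_equal(unname(lipidContacts(mkFrame(4.9))["K398", "PS"]), 1L)
  # 5.1 A beyond every headgroup atom of the molecule: none
  expect_equal(unname(lipidContacts(mkFrame(5.6))["K398", "PS"]), 0L)
  # several atoms of one lipid inside the cutoff still count once
  expect_equal(unname(lipidContacts(mkFrame(3.0))["K398", "PS"]), 1L)
  # unknown lipid residue names are a configuration error
  bad <- mkFrame(3.0)
  a <- atoms(bad); a$resname[a$resname == "POPS"] <- "XXXX"
  expect_error(lipidContacts(MembraneFrame(a)), "configuration error")
})

test_that("contact counts equal the all-pairs oracle on random fixtures", {
  for (s in 1:50) {
    fr <- randomContactFrame(s)
    fast <- lipidContacts(fr)
    slow <- contactOracle(fr)
    expect_identical(fast[rownames(slow), colnames(slow), drop = FALSE],
                     slow)
  }
})

test_that("contact counts grow monotonically with cutoff and stay bounded", {
  fr <- randomContactFrame(99, nLipid = 40, nBasic = 8, span = 25)
  crit <- contactCriteria()
  prev <- NULL
  for (scale in c(0.5, 1, 1.5, 2, 3)) {
    scaled <- lapply(crit, function(cc)
      list(anchor = cc$anchor, cutoff = cc$cutoff * scale))
    counts <- lipidContacts(fr, criteria = scaled)
    if (!is.null(prev)) expect_true(all(counts >= prev))
    prev <- counts
    nPerType <- table(atoms(fr)$resname[atoms(fr)$atom == "P"])
    expect_true(all(counts[, "PS"] <= sum(nPerType["POPS"], na.rm = TRUE)))
    expect_true(all(counts >= 0))
  }
})

test_that("windowed contact statistics match prescribed schedules", {
  sched <- cbind(rep(1L, 10), rep(c(0L, 1L), 5), rep(2L, 10))
  gen <- buildMembraneProteinFrames(schedule = sched, seed = 1)
  series <- lipidContactSeries(gen$trajectory)
  stats <- contactTimeStatistics(series, window = c(-Inf, Inf))
  key <- paste(stats$residue, stats$lipidType)
  types <- gen$truth$residueTypes
  # residue 1 (K398, PIP2): constant 1 -> mean 1, sd 0
  expect_equal(stats$mean[key == paste("K398", types[["K398"]])], 1)
  expect_equal(stats$sd[key == paste("K398", types[["K398"]])], 0)
  # residue 2 (R411, PS): alternating 0/1 -> mean 0.5
  expect_equal(stats$mean[key == paste("R411", types[["R411"]])], 0.5)
  # residue 3 (H449, PS): constant 2
  expect_equal(stats$mean[key == paste("H449", types[["H449"]])], 2)
  # off-type counts stay zero
  expect_equal(stats$mean[key == "K398 PS"], 0)
  # trailing-fraction window selects the last half of frames
  lastHalf <- contactTimeStatistics(series, list(lastFraction = 0.5))
  expect_equal(unique(lastHalf$nFrames), 5)
  expect_error(contactTimeStatistics(series, c(100, 200)), "empty window")
})

test_that("per-frame basic-residue totals count residues, not contacts", {
  sched <- cbind(rep(2L, 4), rep(2L, 4), rep(0L, 4))
  gen <- buildMembraneProteinFrames(schedule = sched, seed = 2)
  series <- lipidContactSeries(gen$trajectory)
  totals <- basicResidueContactTotal(series)
  counts <- contactCounts(totals)
  # K398 contacts 2 PIP2 -> one residue; R411 contacts 2 PS -> one residue
  expect_true(all(counts[, "basic_total", "PIP2"] == 1))
  expect_true(all(counts[, "basic_total", "PS"] == 1))
  expect_true(all(counts[, "basic_total", "PC"] == 0))
})
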