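test_that("accessible lipid concentration halves totals and applies dilution", {
  expect_equal(accessibleLipidConcentration(125), 62.5)
  expect_equal(accessibleLipidConcentration(75, 2, alreadyAccessible = TRUE),
               37.5)
  expect_equal(accessibleLipidConcentration(0), 0)
  expect_error(accessibleLipidConcentration(-1), "non-negative")
  expect_error(accessibleLipidConcentration(10, 0.5), ">= 1")
})

test_that("noiseless competition titrations are recovered exactly", {
  sim <- simulateTitration(ic50 = 620, deltaFmax = 1, offset = 0,
                           noiseSd = 0, seed = 1)
  fit <- fitCompetitionTitration(sim$curve)
  expect_lt(abs(ic50(fit) - 620) / 620, 1e-3)
  expect_lt(abs(deltaFmax(fit) - 1), 1e-3)
  expect_lt(abs(offsetC(fit)), 1e-3)
  # half-saturation identity: model value at x = IC50 is dFmax/2 above C
  predicted <- deltaFmax(fit) *
    (1 - ic50(fit) / (ic50(fit) + ic50(fit))) + offsetC(fit)
  expect_equal(predicted - offsetC(fit), deltaFmax(fit) / 2,
               tolerance = 1e-12)
  # nonzero offset and amplitude round-trip too
  sim2 <- simulateTitration(ic50 = 50, deltaFmax = 3.2, offset = 0.7,
                            noiseSd = 0, seed = 2)
  fit2 <- fitCompetitionTitration(sim2$curve)
  expect_lt(abs(ic50(fit2) - 50) / 50, 1e-3)
  expect_lt(abs(deltaFmax(fit2) - 3.2) / 3.2, 1e-3)
  expect_lt(abs(offsetC(fit2) - 0.7) / 0.7, 1e-3)
})

test_that("IC50 recovery from noisy curves is unbiased within 5 percent", {
  errs <- vapply(1:100, function(s) {
    sim <- simulateTitration(ic50 = 620, noiseSd = 0.02, seed = s)
    abs(ic50(fitCompetitionTitration(sim$curve)) - 620) / 620
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("partition coefficients and free energies reproduce the printed table", {
  inputs <- PartitioningInputs(ki = 1.8, waterMolarity = 55.5,
                               accessibleLipid = 62.5,
                               temperature = 298.15)
  pm <- ic50ToPartitionCoefficient(620, inputs)
  noPip2 <- ic50ToPartitionCoefficient(19, inputs)
  noPsPi <- ic50ToPartitionCoefficient(51, inputs)
  expect_equal(signif(partitionCoefficient(pm) / 1e6, 2), 300)
  # computed 8.5 x 1e6; printed as 8 +/- 1, so integer rounding applies
  expect_equal(round(partitionCoefficient(noPip2) / 1e6), 8)
  expect_equal(signif(partitionCoefficient(noPsPi) / 1e6, 2), 24)
  expect_equal(round(freeEnergy(pm), 1), -11.6)
  expect_equal(round(freeEnergy(noPsPi), 1), -10.1)
  # the weakest-binding composition reproduces within the printed +/- 0.1
  expect_lt(abs(freeEnergy(noPip2) - (-9.4)), 0.1 + 0.051)
  expect_equal(formatKx(partitionCoefficient(pm)), "300")
})

test_that("unit-ratio identities and domain errors hold", {
  inputs <- PartitioningInputs(ki = 1.8, waterMolarity = 1,
                               accessibleLipid = 1e6)
  expect_equal(partitionCoefficient(ic50ToPartitionCoefficient(3.6, inputs)),
               1)
  expect_equal(partitionFreeEnergy(1), 0)
  expect_error(ic50ToPartitionCoefficient(1.8, inputs), "non-positive")
  expect_error(partitionFreeEnergy(0), "positive")
  expect_error(partitionFreeEnergy(-2), "positive")
})

test_that("free energy is strictly decreasing in IC50", {
  inputs <- PartitioningInputs()
  grid <- 1.8 * 10^seq(0.01, 4, length.out = 40)
  dg <- vapply(grid, function(x)
    freeEnergy(ic50ToPartitionCoefficient(x, inputs)), numeric(1))
  expect_true(all(diff(dg) < 0))
})

test_that("lipid-only control subtraction cancels shared drift", {
  x <- c(0, 10, 100, 1000, 5000)
  true <- 1 * (1 - x / (620 + x))
  drift <- 0.05 * log1p(x)
  raw <- TitrationCurve(x, true + drift)
  ctrl <- TitrationCurve(x, 2 + drift)  # different baseline, same drift
  corrected <- applyTitrationControls(raw, ctrl)
  expect_equal(fluorescence(corrected), true, tolerance = 1e-9)
  # identical drift in raw and control leaves a flat curve at raw[0]
  rawFlat <- TitrationCurve(x, 3 + drift)
  corrFlat <- applyTitrationControls(rawFlat, TitrationCurve(x, 7 + drift))
  expect_equal(fluorescence(corrFlat), rep(3, length(x)), tolerance = 1e-12)
  # zero-everywhere control changes nothing
  corrId <- applyTitrationControls(raw, TitrationCurve(x, rep(0, length(x))))
  expect_equal(fluorescence(corrId), fluorescence(raw))
  # non-overlapping grids raise an alignment error
  expect_error(
    applyTitrationControls(raw, TitrationCurve(c(0, 10, 50), c(0, 0, 0))),
    "cover")
})

test_that("buffer-dilution control divides out fractional signal loss", {
  x <- c(0, 10, 100, 1000)
  true <- 1 * (1 - x / (620 + x))
  loss <- c(1, 0.95, 0.9, 0.85)
  raw <- TitrationCurve(x, true * loss)
  lipidCtrl <- TitrationCurve(x, rep(0, 4))
  bufCtrl <- TitrationCurve(x, 10 * loss)
  corrected <- applyTitrationControls(raw, lipidCtrl, bufCtrl)
  expect_equal(fluorescence(corrected), true, tolerance = 1e-12)
})

test_that("normalization maps the fit to unit amplitude and refits unchanged", {
  sim <- simulateTitration(ic50 = 620, deltaFmax = 2.5, offset = 0.4,
                           noiseSd = 0.01, seed = 11)
  fit <- fitCompetitionTitration(sim$curve)
  norm <- normalizeTitration(sim$curve, fit)
  refit <- fitCompetitionTitration(norm)
  expect_equal(ic50(refit), ic50(fit), tolerance = 1e-4)
  expect_equal(deltaFmax(refit), 1, tolerance = 1e-4)
  expect_lt(abs(offsetC(refit)), 1e-4)
  # idempotence: normalizing the normalized curve with its own fit is a no-op
  norm2 <- normalizeTitration(norm, refit)
  expect_equal(fluorescence(norm2), fluorescence(norm), tolerance = 1e-4)
  # boundary values
  expect_equal((fit@offset - offsetC(fit)) / deltaFmax(fit), 0)
})

test_that("degenerate titration inputs are rejected", {
  expect_error(fitCompetitionTitration(
    TitrationCurve(c(0, 1, 2), c(1, 0.5, 0.2))), "4 titration points")
  curve <- TitrationCurve(c(0, 1, 2, 3), c(1, 0.9, 0.8, 0.7),
                          titrantKind = "NaCl")
  expect_error(fitCompetitionTitration(curve), "IP6")
  expect_error(TitrationCurve(c(0, 1, 1), c(1, 1, 1)), "increasing")
  expect_error(TitrationCurve(c(0, 1), c(1, NaN)), "finite")
})
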