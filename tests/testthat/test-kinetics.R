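test_that("replicate averaging is exact for symmetric noise and idempotent", {
  tt <- seq(0, 1, by = 0.01)
  base <- exp(-tt)
  tr1 <- KineticTrace(tt, base + 0.05, deadTime = 0.001)
  tr2 <- KineticTrace(tt, base - 0.05, deadTime = 0.0014)
  avg <- averageReplicateTraces(list(tr1, tr2))
  expect_equal(traceSignal(avg), base, tolerance = 1e-12)
  expect_equal(deadTime(avg), 0.0014)
  expect_equal(avg@nReplicates, 2L)
  same <- averageReplicateTraces(list(tr1, tr1))
  expect_equal(traceSignal(same), traceSignal(tr1))
  expect_error(averageReplicateTraces(
    list(tr1, KineticTrace(tt + 0.001, base))), "time base")
})

test_that("averaging n replicates reduces noise variance about n-fold", {
  tt <- seq(0, 1, by = 0.005)
  base <- exp(-tt)
  ratio <- vapply(1:50, function(s) {
    set.seed(s)
    sigma <- 0.05
    reps <- lapply(1:8, function(i)
      KineticTrace(tt, base + rnorm(length(tt), 0, sigma)))
    avg <- averageReplicateTraces(reps)
    var(traceSignal(avg) - base) / sigma^2
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1 / 8), 0.3 / 8)
})

test_that("association fits recover the generating rate and closed forms", {
  sim <- simulateKineticTrace("association", rates = 30, noiseSd = 0,
                              seed = 1)
  fit <- fitAssociation(sim$trace)
  expect_lt(abs(kObs(fit) - 30) / 30, 1e-3)
  expect_lt(abs(deltaFmax(fit) - 1), 1e-3)
  # closed forms of the fitted model
  model <- function(t) deltaFmax(fit) * (1 - exp(-kObs(fit) * t)) +
    offsetC(fit)
  expect_equal(model(1 / kObs(fit)) - offsetC(fit),
               deltaFmax(fit) * (1 - exp(-1)), tolerance = 1e-12)
  halfRise <- log(2) / kObs(fit)
  expect_equal(model(halfRise) - offsetC(fit), deltaFmax(fit) / 2,
               tolerance = 1e-12)
})

test_that("noiseless biexponential dissociation is recovered to 0.5 percent", {
  sim <- simulateKineticTrace("double", rates = c(1.0, 0.14),
                              amplitudes = c(0.35, 0.65), noiseSd = 0,
                              seed = 1)
  fit <- fitDissociation(sim$trace, model = "auto")
  expect_equal(fit@model, "double")
  expect_lt(max(abs(offRates(fit) - c(1.0, 0.14)) / c(1.0, 0.14)), 0.005)
  expect_lt(max(abs(amplitudeFractions(fit) - c(35, 65))), 0.5)
  expect_equal(sum(amplitudeFractions(fit)), 100, tolerance = 1e-9)
  expect_true(offRates(fit)[1] > offRates(fit)[2])
})

test_that("model selection picks single for single and double for resolved biexponentials", {
  nSingle <- sum(vapply(1:20, function(s) {
    sim <- simulateKineticTrace("single", rates = 1, noiseSd = 0, seed = s)
    fitDissociation(sim$trace, "auto")@model == "single"
  }, logical(1)))
  expect_equal(nSingle, 20L)
  nDouble <- sum(vapply(1:20, function(s) {
    sim <- simulateKineticTrace("double", rates = c(1.0, 0.2),
                                amplitudes = c(0.35, 0.65),
                                noiseSd = 0.01, seed = s)
    fitDissociation(sim$trace, "auto")@model == "double"
  }, logical(1)))
  expect_gte(nDouble, 19L)
})

test_that("biexponential rates are recovered within 10 percent under noise", {
  errs <- vapply(1:100, function(s) {
    sim <- simulateKineticTrace("double", rates = c(1.0, 0.14),
                                amplitudes = c(0.35, 0.65),
                                noiseSd = 0.02, seed = s)
    fit <- fitDissociation(sim$trace, model = "double")
    max(abs(offRates(fit) - c(1.0, 0.14)) / c(1.0, 0.14))
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("mole-fraction association rate constants follow the worked example", {
  inputs <- PartitioningInputs(accessibleLipid = 37.5)
  res <- associationRateConstant(30, 1.0, inputs)
  expect_equal(signif(konX(res) / 1e6, 2), 43)
  # limiting form with no dissociation
  res0 <- associationRateConstant(30, 0, inputs)
  expect_equal(konX(res0), 30 * 55.5 / 37.5e-6)
  # unit ratio: water molarity equal to accessible lipid molarity
  unit <- PartitioningInputs(waterMolarity = 1, accessibleLipid = 1e6)
  expect_equal(konX(associationRateConstant(30, 1, unit)), 29)
  expect_error(associationRateConstant(1, 2, inputs), "non-positive")
})

test_that("kon,x is linear in kObs and halves when lipid doubles", {
  inputs <- PartitioningInputs(accessibleLipid = 37.5)
  k1 <- konX(associationRateConstant(10, 1, inputs))
  k2 <- konX(associationRateConstant(19, 1, inputs))
  expect_equal(k2 / k1, 2, tolerance = 1e-12)
  doubled <- PartitioningInputs(accessibleLipid = 75)
  expect_equal(konX(associationRateConstant(10, 1, doubled)), k1 / 2,
               tolerance = 1e-12)
})

test_that("points before the dead time never influence fits", {
  sim <- simulateKineticTrace("double", rates = c(1.0, 0.14),
                              amplitudes = c(0.35, 0.65), noiseSd = 0.005,
                              seed = 3, deadTime = 0.05)
  trace <- sim$trace
  corrupt <- trace
  pre <- traceTime(trace) < deadTime(trace)
  sig <- traceSignal(trace)
  sig[pre] <- 1e6  # wildly corrupted instrument transient
  corrupt <- KineticTrace(traceTime(trace), sig,
                          deadTime = deadTime(trace))
  f1 <- fitDissociation(trace, "double")
  f2 <- fitDissociation(corrupt, "double")
  expect_identical(offRates(f1), offRates(f2))
  a1 <- suppressWarnings(fitAssociation(trace))
  a2 <- suppressWarnings(fitAssociation(corrupt))
  expect_identical(kObs(a1), kObs(a2))
})

test_that("trace normalization yields unit total amplitude and stable rates", {
  sim <- simulateKineticTrace("double", rates = c(1.0, 0.14),
                              amplitudes = c(0.7, 1.3), offset = 0.2,
                              noiseSd = 0.01, seed = 5)
  fit <- fitDissociation(sim$trace, "double")
  norm <- normalizeTrace(sim$trace, fit)
  refit <- fitDissociation(norm, "double")
  expect_equal(offRates(refit), offRates(fit), tolerance = 1e-4)
  expect_equal(sum(amplitudes(refit)), 1, tolerance = 1e-4)
  # extrapolated dissociation signal at t = 0 is 1 after normalization
  expect_equal(sum(amplitudes(refit)) * 1 + offsetC(refit), 1,
               tolerance = 1e-6)
  # association normalization: F = C maps to 0
  simA <- simulateKineticTrace("association", rates = 30, offset = 0.5,
                               noiseSd = 0, seed = 6)
  fitA <- fitAssociation(simA$trace)
  normA <- normalizeTrace(simA$trace, fitA)
  expect_equal(traceSignal(normA)[1], 0, tolerance = 1e-6)
})
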