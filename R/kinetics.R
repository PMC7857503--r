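#' Average replicate stopped-flow traces
#'
#' Pointwise mean of replicate shots sharing a common time base (per-point
#' tolerance 1e-9 s). The result's dead time is the maximum over inputs and
#' the replicate count is recorded.
#'
#' @param traces list of \linkS4class{KineticTrace} objects.
#' @return A \linkS4class{KineticTrace} with averaged signal.
#' @export
averageReplicateTraces <- function(traces) {
  stopifnot(length(traces) >= 2,
            all(vapply(traces, is, logical(1), "KineticTrace")))
  t0 <- traces[[1]]@time
  for (tr in traces[-1]) {
    if (length(tr@time) != length(t0) || any(abs(tr@time - t0) > 1e-9))
      stop("replicate traces do not share a common time base")
  }
  sig <- rowMeans(vapply(traces, function(tr) tr@signal,
                         numeric(length(t0))))
  new("KineticTrace", time = t0, signal = sig,
      deadTime = max(vapply(traces, function(tr) tr@deadTime, numeric(1))),
      nReplicates = sum(vapply(traces, function(tr) tr@nReplicates,
                               integer(1))))
}

# points usable for fitting: at or beyond the instrument dead time
.liveRegion <- function(trace) {
  keep <- trace@time >= trace@deadTime - 1e-12
  list(t = trace@time[keep], y = trace@signal[keep])
}

#' Fit a single-exponential association trace
#'
#' Fits \deqn{F = \Delta F_{max}(1 - e^{-k_{obs} t}) + C} to the trace on
#' t >= dead time. A warning is issued when the fitted span covers fewer
#' than 3 relaxation times.
#'
#' @param trace a \linkS4class{KineticTrace}.
#' @return An \linkS4class{AssociationFit}.
#' @examples
#' sim <- simulateKineticTrace(model = "association", rates = 30,
#'                             noiseSd = 0, seed = 1)
#' kObs(fitAssociation(sim$trace))
#' @export
fitAssociation <- function(trace) {
  stopifnot(is(trace, "KineticTrace"))
  lr <- .liveRegion(trace)
  t <- lr$t; y <- lr$y
  if (length(t) < 4) stop("insufficient data beyond the dead time")
  amp0 <- max(y[length(y)] - y[1], 1e-6)
  # crude rate guess from the time of half rise
  halfT <- t[which(y - y[1] >= amp0 / 2)[1]]
  k0 <- if (is.na(halfT) || halfT <= 0) 1 / stats::median(t) else log(2) / halfT
  fit <- tryCatch(
    .lmFit(
      start = list(deltaFmax = amp0, kObs = k0, offset = y[1]),
      lower = c(deltaFmax = 0, kObs = 1e-12, offset = -Inf),
      fn = function(p)
        y - (p$deltaFmax * (1 - exp(-p$kObs * t)) + p$offset)),
    error = function(e) stop("association fit failed to converge: ",
                             conditionMessage(e)))
  if (max(t) * fit$par["kObs"] < 3)
    warning("trace spans fewer than 3 relaxation times (3/kObs); ",
            "kObs may be poorly determined")
  new("AssociationFit", kObs = unname(fit$par["kObs"]),
      deltaFmax = unname(fit$par["deltaFmax"]),
      offset = unname(fit$par["offset"]),
      stdErrors = fit$se, rss = fit$rss)
}

#' Fit a single- or double-exponential dissociation trace
#'
#' Single model: \deqn{F = \Delta F_{max} e^{-k t} + C}. Double model:
#' \deqn{F = \Delta F_{max,1} e^{-k_1 t} + \Delta F_{max,2} e^{-k_2 t} + C}.
#' With \code{model = "auto"} both candidates are fitted and the one with the
#' lower corrected Akaike information criterion (AICc) is returned; the AICc
#' of both candidates is recorded in the result. A double fit whose two rates
#' collapse within 1 percent of each other falls back to the single model
#' with a warning.
#'
#' The double-exponential starting values come from log-linear peeling: the
#' slow component is estimated from the tail of log(F - C), then the fast
#' component from the residual of the early points.
#'
#' @param trace a \linkS4class{KineticTrace}.
#' @param model \code{"single"}, \code{"double"} or \code{"auto"}.
#' @return A \linkS4class{DissociationFit} with rates fast-first.
#' @examples
#' sim <- simulateKineticTrace(model = "double", rates = c(1.0, 0.14),
#'                             amplitudes = c(0.35, 0.65), noiseSd = 0,
#'                             seed = 1)
#' fitDissociation(sim$trace, model = "auto")
#' @export
fitDissociation <- function(trace, model = c("auto", "single", "double")) {
  stopifnot(is(trace, "KineticTrace"))
  model <- match.arg(model)
  lr <- .liveRegion(trace)
  if (length(lr$t) < 6)
    stop("insufficient data: at least 6 points beyond the dead time")
  fits <- list()
  if (model %in% c("single", "auto"))
    fits$single <- tryCatch(.fitDissocSingle(lr$t, lr$y),
                            error = function(e) e)
  if (model %in% c("double", "auto"))
    fits$double <- tryCatch(.fitDissocDouble(lr$t, lr$y),
                            error = function(e) e)
  ok <- !vapply(fits, inherits, logical(1), "condition")
  if (!any(ok))
    stop("dissociation fit failed to converge for all candidate models: ",
         conditionMessage(fits[[1]]))
  fits <- fits[ok]

  # degenerate double fit: rates within 1% of each other, or one component
  # carrying a vanishing share of the amplitude
  if ("double" %in% names(fits)) {
    r <- fits$double@rates
    a <- fits$double@amplitudes
    if (abs(r[1] - r[2]) / r[1] < 0.01) {
      if (model == "double")
        warning("double-exponential rates collapsed within 1%; ",
                "falling back to single-exponential model")
      fits$double <- NULL
    } else if (model == "auto" && min(a) / sum(a) < 1e-3) {
      fits$double <- NULL
    }
    if (!length(fits)) fits$single <- .fitDissocSingle(lr$t, lr$y)
  }
  # floor the RSS at numerical zero so machine-precision fits of noiseless
  # data compare by parameter count rather than by rounding noise
  rssFloor <- length(lr$t) * (1e-9 * max(diff(range(lr$y)), 1))^2
  aicc <- vapply(fits, function(f) .aicc(max(f@rss, rssFloor), length(lr$t),
                                         .nFitParams(f)), numeric(1))
  best <- fits[[which.min(aicc)]]
  best@aicc <- aicc
  best
}

.nFitParams <- function(fit) 1L + 2L * length(fit@rates)

# corrected Akaike information criterion from a least-squares fit
.aicc <- function(rss, n, k) {
  # +1 for the residual variance parameter
  p <- k + 1
  aic <- n * log(rss / n) + 2 * p
  if (n - p - 1 > 0) aic + 2 * p * (p + 1) / (n - p - 1) else Inf
}

.fitDissocSingle <- function(t, y) {
  off0 <- min(y)
  amp0 <- max(y[1] - off0, 1e-6)
  pos <- y - off0 + amp0 * 1e-3
  k0 <- max(-stats::coef(stats::lm(log(pos) ~ t))[[2]], 1e-3)
  fit <- .lmFit(
    start = list(a1 = amp0, k1 = k0, offset = off0),
    lower = c(a1 = 0, k1 = 1e-12, offset = -Inf),
    fn = function(p) y - (p$a1 * exp(-p$k1 * t) + p$offset))
  new("DissociationFit", model = "single",
      rates = unname(fit$par["k1"]), amplitudes = unname(fit$par["a1"]),
      offset = unname(fit$par["offset"]), stdErrors = fit$se,
      rss = fit$rss, aicc = numeric(0))
}

# log-linear peeling start values for the biexponential model
.peelStart <- function(t, y) {
  off0 <- min(y)
  pos <- pmax(y - off0, max(y - off0) * 1e-6)
  n <- length(t)
  tail <- seq.int(max(1L, floor(n * 0.6)), n)
  slowFit <- stats::lm(log(pos[tail]) ~ t[tail])
  kSlow <- max(-stats::coef(slowFit)[[2]], 1e-4)
  aSlow <- max(exp(stats::coef(slowFit)[[1]]), 1e-8)
  resid <- pos - aSlow * exp(-kSlow * t)
  head <- which(resid > max(resid) * 1e-3)
  head <- head[head <= ceiling(n * 0.5)]
  if (length(head) >= 3) {
    fastFit <- stats::lm(log(resid[head]) ~ t[head])
    kFast <- max(-stats::coef(fastFit)[[2]], kSlow * 3)
    aFast <- max(exp(stats::coef(fastFit)[[1]]), 1e-8)
  } else {
    kFast <- kSlow * 10
    aFast <- max(pos[1] - aSlow, 1e-6)
  }
  list(a1 = aFast, k1 = kFast, a2 = aSlow, k2 = kSlow, offset = off0)
}

.fitDissocDouble <- function(t, y) {
  start <- .peelStart(t, y)
  fit <- .lmFit(
    start = start,
    lower = c(a1 = 0, k1 = 1e-12, a2 = 0, k2 = 1e-12, offset = -Inf),
    fn = function(p)
      y - (p$a1 * exp(-p$k1 * t) + p$a2 * exp(-p$k2 * t) + p$offset),
    maxiter = 500)
  co <- fit$par
  rates <- c(co[["k1"]], co[["k2"]])
  amps <- c(co[["a1"]], co[["a2"]])
  ord <- order(rates, decreasing = TRUE)
  # reorder the per-component standard errors to match fast-first storage
  se <- fit$se
  se[c("k1", "k2")] <- fit$se[c("k1", "k2")][ord]
  se[c("a1", "a2")] <- fit$se[c("a1", "a2")][ord]
  new("DissociationFit", model = "double",
      rates = rates[ord], amplitudes = amps[ord],
      offset = co[["offset"]], stdErrors = se,
      rss = fit$rss, aicc = numeric(0))
}

#' Mole-fraction association rate constant
#'
#' \deqn{k_{on,x} = (k_{obs} - k_{off})\,[H_2O]/[L]} with the bulk water
#' concentration in molar and the accessible lipid concentration in
#' micromolar (converted internally). The accessible lipid should reflect
#' concentrations after mixing (equal-volume stopped-flow mixing halves the
#' syringe concentration).
#'
#' @param kObs observed association rate, 1/s.
#' @param kOff dissociation rate to subtract, 1/s. Which dissociation
#'   component (fast, slow, or amplitude-weighted) to use is the caller's
#'   explicit choice.
#' @param inputs a \linkS4class{PartitioningInputs}; only waterMolarity and
#'   accessibleLipid are used.
#' @return A \linkS4class{RateResult}.
#' @examples
#' res <- associationRateConstant(30, 1.0,
#'   PartitioningInputs(accessibleLipid = 37.5))
#' konX(res) / 1e6  # ~43
#' @export
associationRateConstant <- function(kObs, kOff, inputs) {
  stopifnot(is(inputs, "PartitioningInputs"))
  if (kOff < 0) stop("kOff must be non-negative")
  if (kObs <= kOff)
    stop("non-positive rate: kObs (", kObs, ") must exceed kOff (", kOff, ")")
  konX <- (kObs - kOff) * inputs@waterMolarity /
    (inputs@accessibleLipid * 1e-6)
  new("RateResult", konX = konX, kObs = kObs, kOff = kOff, inputs = inputs)
}

#' Normalize a kinetic trace to unit amplitude and zero offset
#'
#' Maps the signal to (F - C) / total amplitude, where the offset and
#' amplitude(s) come from an association or dissociation fit of the trace.
#'
#' @param trace a \linkS4class{KineticTrace}.
#' @param fit an \linkS4class{AssociationFit} or
#'   \linkS4class{DissociationFit}.
#' @return The normalized \linkS4class{KineticTrace}.
#' @export
normalizeTrace <- function(trace, fit) {
  stopifnot(is(trace, "KineticTrace"))
  if (is(fit, "AssociationFit")) {
    total <- fit@deltaFmax; off <- fit@offset
  } else if (is(fit, "DissociationFit")) {
    total <- sum(fit@amplitudes); off <- fit@offset
  } else stop("fit must be an AssociationFit or DissociationFit")
  if (total <= 0) stop("degenerate amplitude: total amplitude must be positive")
  initialize(trace, signal = (trace@signal - off) / total)
}
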