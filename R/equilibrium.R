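#' Gas constant in kcal/(mol K)
#' @keywords internal
.GAS_CONSTANT_KCAL <- 1.987e-3

#' Accessible lipid concentration
#'
#' Only the outer-leaflet lipids of a sonicated unilamellar vesicle are
#' available for protein binding; the accessible pool is approximated as
#' one-half of the total lipid. A dilution factor accounts for mixing steps
#' (e.g. equal-volume stopped-flow mixing halves the syringe concentration).
#'
#' @param totalLipid total bulk lipid concentration, micromolar.
#' @param dilutionFactor dilution applied to the stated concentration
#'   (>= 1; equal-volume mixing is 2).
#' @param alreadyAccessible set TRUE when \code{totalLipid} is already
#'   expressed as accessible (outer-leaflet) lipid, skipping the halving.
#' @return Accessible lipid concentration in micromolar.
#' @examples
#' accessibleLipidConcentration(125)                            # 62.5
#' accessibleLipidConcentration(75, 2, alreadyAccessible = TRUE) # 37.5
#' @export
accessibleLipidConcentration <- function(totalLipid, dilutionFactor = 1,
                                         alreadyAccessible = FALSE) {
  if (any(totalLipid < 0)) stop("totalLipid must be non-negative")
  if (any(dilutionFactor < 1)) stop("dilutionFactor must be >= 1")
  half <- if (alreadyAccessible) 1 else 2
  totalLipid / (half * dilutionFactor)
}

#' Fit a hyperbolic competition titration
#'
#' Fits the single-site competitive-inhibition model
#' \deqn{F = \Delta F_{max}\,(1 - x/(IC_{50} + x)) + C}
#' to a titration curve by nonlinear least squares. Starting values default
#' to: IC50 at the titrant concentration where half the total signal drop has
#' occurred, amplitude as F(first) - F(last), offset as F(last); all
#' parameters are bounded below by zero (IC50 by a small positive value).
#'
#' @param curve a \linkS4class{TitrationCurve} with titrantKind \code{"IP6"}.
#' @param init optional named list/vector with any of \code{deltaFmax},
#'   \code{ic50}, \code{offset} starting values.
#' @return A \linkS4class{CompetitionFit}.
#' @examples
#' sim <- simulateTitration(ic50 = 620, noiseSd = 0, seed = 1)
#' fit <- fitCompetitionTitration(sim$curve)
#' ic50(fit)
#' @export
fitCompetitionTitration <- function(curve, init = NULL) {
  stopifnot(is(curve, "TitrationCurve"))
  if (curve@titrantKind != "IP6")
    stop("competition fitting applies to IP6 titrations")
  x <- curve@titrantConc
  y <- curve@fluorescence
  if (length(x) < 4)
    stop("insufficient data: at least 4 titration points required")
  start <- list(
    deltaFmax = y[1] - y[length(y)],
    ic50 = .halfDropConc(x, y),
    offset = y[length(y)]
  )
  for (nm in names(init)) start[[nm]] <- init[[nm]]
  if (start$deltaFmax <= 0) start$deltaFmax <- max(diff(range(y)), 1e-6)
  if (!is.finite(start$ic50) || start$ic50 <= 0)
    start$ic50 <- stats::median(x[x > 0])
  fit <- tryCatch(
    .lmFit(
      start = list(deltaFmax = start$deltaFmax, ic50 = start$ic50,
                   offset = start$offset),
      lower = c(deltaFmax = 0, ic50 = 1e-12, offset = -Inf),
      fn = function(p)
        y - (p$deltaFmax * (1 - x / (p$ic50 + x)) + p$offset)),
    error = function(e) stop("competition fit failed to converge: ",
                             conditionMessage(e)))
  new("CompetitionFit",
      ic50 = unname(fit$par["ic50"]),
      deltaFmax = unname(fit$par["deltaFmax"]),
      offset = unname(fit$par["offset"]),
      stdErrors = fit$se,
      rss = fit$rss,
      nPoints = length(x))
}

# titrant concentration at which half the total signal drop has occurred
.halfDropConc <- function(x, y) {
  target <- (y[1] + y[length(y)]) / 2
  below <- which(y <= target)
  if (!length(below)) return(stats::median(x[x > 0]))
  i <- below[1]
  if (i == 1) return(max(x[1], min(x[x > 0])))
  # linear interpolation between bracketing points
  x0 <- x[i - 1]; x1 <- x[i]; y0 <- y[i - 1]; y1 <- y[i]
  if (y1 == y0) return(x1)
  x0 + (target - y0) * (x1 - x0) / (y1 - y0)
}

#' Convert an IC50 to a mole-fraction partition coefficient
#'
#' \deqn{K_x = (IC_{50}/K_I - 1)\,[H_2O]/[L]}
#' where \eqn{K_I} is the protein-inhibitor dissociation constant,
#' \eqn{[H_2O]} the bulk water concentration and \eqn{[L]} the accessible
#' lipid concentration. IC50, \eqn{K_I} and \eqn{[L]} are in micromolar,
#' \eqn{[H_2O]} in molar; units are reconciled internally.
#'
#' @param ic50 half-displacement titrant concentration, micromolar.
#' @param inputs a \linkS4class{PartitioningInputs}.
#' @return A \linkS4class{PartitioningResult} carrying Kx and deltaG.
#' @examples
#' res <- ic50ToPartitionCoefficient(620, PartitioningInputs())
#' partitionCoefficient(res)  # ~3.05e8
#' @export
ic50ToPartitionCoefficient <- function(ic50, inputs = PartitioningInputs()) {
  stopifnot(is(inputs, "PartitioningInputs"))
  if (ic50 <= inputs@ki)
    stop("non-positive partition coefficient: IC50 (", ic50,
         " uM) does not exceed the inhibitor dissociation constant (",
         inputs@ki, " uM)")
  kx <- (ic50 / inputs@ki - 1) *
    inputs@waterMolarity / (inputs@accessibleLipid * 1e-6)
  new("PartitioningResult",
      kx = kx,
      deltaG = partitionFreeEnergy(kx, inputs@temperature),
      gasConstant = .GAS_CONSTANT_KCAL,
      inputs = inputs)
}

#' Binding free energy from a partition coefficient
#'
#' \deqn{\Delta G^\circ = -R T \ln K_x} with
#' R = 1.987e-3 kcal/(mol K).
#'
#' @param kx dimensionless mole-fraction partition coefficient, > 0.
#' @param temperature absolute temperature in kelvin.
#' @return Free energy in kcal/mol.
#' @examples
#' partitionFreeEnergy(3.05e8)  # about -11.6
#' @export
partitionFreeEnergy <- function(kx, temperature = 298.15) {
  if (any(kx <= 0)) stop("kx must be positive")
  -.GAS_CONSTANT_KCAL * temperature * log(kx)
}

#' Apply lipid-only and buffer-dilution controls to a titration
#'
#' The lipid-only control measures titrant effects on probe fluorescence; its
#' drift (relative to its own first point) is subtracted from the raw curve.
#' An optional buffer-dilution control corrects multiplicatively for signal
#' loss on buffer addition: the corrected signal is divided by the control's
#' fractional signal profile (control / control[1]).
#'
#' Controls measured on a different titrant grid are linearly interpolated
#' onto the raw grid; their range must cover it.
#'
#' @param raw the raw \linkS4class{TitrationCurve}.
#' @param lipidOnlyControl control curve of titrant added to lipid alone.
#' @param bufferDilutionControl optional curve of signal vs titrant for
#'   buffer-only additions.
#' @return A corrected \linkS4class{TitrationCurve} on the raw grid.
#' @export
applyTitrationControls <- function(raw, lipidOnlyControl,
                                   bufferDilutionControl = NULL) {
  stopifnot(is(raw, "TitrationCurve"), is(lipidOnlyControl, "TitrationCurve"))
  ctrl <- .controlOnGrid(lipidOnlyControl, raw@titrantConc)
  corrected <- raw@fluorescence - (ctrl - ctrl[1])
  if (!is.null(bufferDilutionControl)) {
    bd <- .controlOnGrid(bufferDilutionControl, raw@titrantConc)
    frac <- bd / bd[1]
    if (any(frac <= 0)) stop("degenerate buffer-dilution control profile")
    corrected <- corrected / frac
  }
  initialize(raw, fluorescence = corrected)
}

.controlOnGrid <- function(control, grid) {
  cx <- control@titrantConc
  if (min(grid) < min(cx) - 1e-9 || max(grid) > max(cx) + 1e-9)
    stop("control curve does not cover the raw titrant range (",
         min(grid), " - ", max(grid), ")")
  stats::approx(cx, control@fluorescence, xout = grid, rule = 1)$y
}

#' Normalize a titration curve to unit amplitude and zero offset
#'
#' Maps each fluorescence value to (F - C) / dFmax using the fitted offset
#' and amplitude, so the curve starts near 1 and decays toward 0.
#'
#' @param curve a \linkS4class{TitrationCurve}.
#' @param fit the \linkS4class{CompetitionFit} of that curve.
#' @return The normalized \linkS4class{TitrationCurve}.
#' @export
normalizeTitration <- function(curve, fit) {
  stopifnot(is(curve, "TitrationCurve"), is(fit, "CompetitionFit"))
  if (fit@deltaFmax <= 0)
    stop("degenerate amplitude: deltaFmax must be positive")
  initialize(curve,
             fluorescence = (curve@fluorescence - fit@offset) / fit@deltaFmax)
}

#' Format a partition coefficient for tabular reporting
#'
#' Reports Kx in units of 1e6 at two significant figures (so 3.05e8 renders
#' as "300").
#'
#' @param kx dimensionless partition coefficient.
#' @return character.
#' @export
formatKx <- function(kx) {
  format(signif(kx / 1e6, 2), scientific = FALSE, trim = TRUE)
}

#' Format a binding free energy at one decimal place
#'
#' @param deltaG free energy in kcal/mol.
#' @return character.
#' @export
formatDeltaG <- function(deltaG) {
  sprintf("%.1f", deltaG)
}
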