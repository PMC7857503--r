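#' @name accessors
#' @title Accessors for C2MemBind data classes
#' @description Slot accessors for the package's S4 data containers.
#' @param object an object of the documented class.
NULL

#' @rdname accessors
#' @export
setGeneric("titrantConc", function(object) standardGeneric("titrantConc"))
#' @rdname accessors
#' @export
setMethod("titrantConc", "TitrationCurve", function(object) object@titrantConc)

#' @rdname accessors
#' @export
setGeneric("fluorescence", function(object) standardGeneric("fluorescence"))
#' @rdname accessors
#' @export
setMethod("fluorescence", "TitrationCurve",
          function(object) object@fluorescence)

#' @rdname accessors
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))
#' @rdname accessors
#' @export
setMethod("ic50", "CompetitionFit", function(object) object@ic50)

#' @rdname accessors
#' @export
setGeneric("deltaFmax", function(object) standardGeneric("deltaFmax"))
#' @rdname accessors
#' @export
setMethod("deltaFmax", "CompetitionFit", function(object) object@deltaFmax)
#' @rdname accessors
#' @export
setMethod("deltaFmax", "AssociationFit", function(object) object@deltaFmax)

#' @rdname accessors
#' @export
setGeneric("offsetC", function(object) standardGeneric("offsetC"))
#' @rdname accessors
#' @export
setMethod("offsetC", "CompetitionFit", function(object) object@offset)
#' @rdname accessors
#' @export
setMethod("offsetC", "AssociationFit", function(object) object@offset)
#' @rdname accessors
#' @export
setMethod("offsetC", "DissociationFit", function(object) object@offset)

#' @rdname accessors
#' @export
setGeneric("stdErrors", function(object) standardGeneric("stdErrors"))
#' @rdname accessors
#' @export
setMethod("stdErrors", "CompetitionFit", function(object) object@stdErrors)
#' @rdname accessors
#' @export
setMethod("stdErrors", "AssociationFit", function(object) object@stdErrors)
#' @rdname accessors
#' @export
setMethod("stdErrors", "DissociationFit", function(object) object@stdErrors)

#' @rdname accessors
#' @export
setGeneric("partitionCoefficient",
           function(object) standardGeneric("partitionCoefficient"))
#' @rdname accessors
#' @export
setMethod("partitionCoefficient", "PartitioningResult",
          function(object) object@kx)

#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))
#' @rdname accessors
#' @export
setMethod("freeEnergy", "PartitioningResult", function(object) object@deltaG)

#' @rdname accessors
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))
#' @rdname accessors
#' @export
setMethod("traceTime", "KineticTrace", function(object) object@time)

#' @rdname accessors
#' @export
setGeneric("traceSignal", function(object) standardGeneric("traceSignal"))
#' @rdname accessors
#' @export
setMethod("traceSignal", "KineticTrace", function(object) object@signal)

#' @rdname accessors
#' @export
setGeneric("deadTime", function(object) standardGeneric("deadTime"))
#' @rdname accessors
#' @export
setMethod("deadTime", "KineticTrace", function(object) object@deadTime)

#' @rdname accessors
#' @export
setGeneric("kObs", function(object) standardGeneric("kObs"))
#' @rdname accessors
#' @export
setMethod("kObs", "AssociationFit", function(object) object@kObs)

#' @rdname accessors
#' @export
setGeneric("offRates", function(object) standardGeneric("offRates"))
#' @rdname accessors
#' @export
setMethod("offRates", "DissociationFit", function(object) object@rates)

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setMethod("amplitudes", "DissociationFit", function(object) object@amplitudes)

#' Amplitude fractions of a dissociation fit
#'
#' Percentages of the total amplitude attributed to each exponential
#' component, fast component first; sums to 100.
#'
#' @param object a \linkS4class{DissociationFit}.
#' @return numeric vector of percentages.
#' @export
setGeneric("amplitudeFractions",
           function(object) standardGeneric("amplitudeFractions"))
#' @rdname amplitudeFractions
#' @export
setMethod("amplitudeFractions", "DissociationFit", function(object) {
  100 * object@amplitudes / sum(object@amplitudes)
})

#' @rdname accessors
#' @export
setGeneric("konX", function(object) standardGeneric("konX"))
#' @rdname accessors
#' @export
setMethod("konX", "RateResult", function(object) object@konX)

#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "MembraneFrame", function(object) object@atoms)

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "MembraneTrajectory", function(object) object@frames)

#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setMethod("positions", "PoseSet", function(object) object@positions)

#' @rdname accessors
#' @export
setGeneric("contactCounts", function(object) standardGeneric("contactCounts"))
#' @rdname accessors
#' @export
setMethod("contactCounts", "ContactSeries", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setMethod("frameTimes", "ContactSeries", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("frameTimes", "MembraneTrajectory", function(object)
  vapply(object@frames, function(f) f@time, numeric(1)))

#' @rdname accessors
#' @export
setMethod("length", "MembraneTrajectory", function(x) length(x@frames))
#' @rdname accessors
#' @export
setMethod("length", "PoseSet", function(x) nrow(x@positions))

setMethod("show", "TitrationCurve", function(object) {
  cat(sprintf("TitrationCurve: %d points, titrant %s, composition %s\n",
              length(object@titrantConc), object@titrantKind,
              object@compositionLabel))
  cat(sprintf("  titrant range: %g - %g, protein %g uM, total lipid %g uM\n",
              min(object@titrantConc), max(object@titrantConc),
              object@proteinConc, object@totalLipidConc))
})

setMethod("show", "CompetitionFit", function(object) {
  cat(sprintf(
    "CompetitionFit: IC50 = %.4g +/- %.2g, dFmax = %.4g, C = %.4g (n = %d)\n",
    object@ic50, object@stdErrors[["ic50"]], object@deltaFmax,
    object@offset, object@nPoints))
})

setMethod("show", "PartitioningResult", function(object) {
  cat(sprintf("PartitioningResult: Kx = %.3g (%s x 1e6), deltaG = %.2f kcal/mol\n",
              object@kx, formatKx(object@kx), object@deltaG))
})

setMethod("show", "KineticTrace", function(object) {
  cat(sprintf(
    "KineticTrace: %d points, t = %.4g - %.4g s, dead time %.4g s, %d replicates\n",
    length(object@time), min(object@time), max(object@time),
    object@deadTime, object@nReplicates))
})

setMethod("show", "AssociationFit", function(object) {
  cat(sprintf("AssociationFit: kObs = %.4g /s, dFmax = %.4g, C = %.4g\n",
              object@kObs, object@deltaFmax, object@offset))
})

setMethod("show", "DissociationFit", function(object) {
  fr <- amplitudeFractions(object)
  comps <- paste(sprintf("%.3g /s (%.0f%% amp)", object@rates, fr),
                 collapse = ", ")
  cat(sprintf("DissociationFit (%s): %s, C = %.4g\n",
              object@model, comps, object@offset))
})

setMethod("show", "RateResult", function(object) {
  cat(sprintf("RateResult: kon,x = %.4g /s (%.3g x 1e6)\n",
              object@konX, object@konX / 1e6))
})

setMethod("show", "MembraneFrame", function(object) {
  cat(sprintf("MembraneFrame: %d atoms, %d residues, t = %g ns%s\n",
              nrow(object@atoms),
              length(unique(paste(object@atoms$segid, object@atoms$resno))),
              object@time,
              if (length(object@box))
                sprintf(", box %g x %g x %g A", object@box[1], object@box[2],
                        object@box[3]) else ""))
})

setMethod("show", "MembraneTrajectory", function(object) {
  cat(sprintf("MembraneTrajectory: %d frames\n", length(object@frames)))
})

setMethod("show", "ContactSeries", function(object) {
  d <- dim(object@counts)
  cat(sprintf("ContactSeries: %d frames x %d residues x %d lipid types\n",
              d[1], d[2], d[3]))
})

setMethod("show", "PoseSet", function(object) {
  cat(sprintf("PoseSet: %d poses\n", nrow(object@positions)))
})

setMethod("show", "ModifiedPeptide", function(object) {
  mods <- if (length(object@siteModifications))
    paste(sprintf("%s@%s",
                  vapply(object@siteModifications, function(m) m@name,
                         character(1)),
                  names(object@siteModifications)), collapse = ", ")
  else "none"
  cat(sprintf("ModifiedPeptide: %s (modifications: %s)\n",
              object@sequence, mods))
})
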