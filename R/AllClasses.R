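#' @import methods
NULL

#' Equilibrium competition titration curve
#'
#' Ordered (titrant concentration, fluorescence) observations from a
#' protein-to-membrane FRET competition titration, together with the assay
#' context (titrant identity, protein concentration, total lipid, liposome
#' composition label).
#'
#' @slot titrantConc numeric, titrant concentrations in micromolar (IP6) or
#'   millimolar (NaCl); non-negative, strictly increasing.
#' @slot fluorescence numeric, fluorescence intensities (arbitrary units).
#' @slot titrantKind character, one of \code{"IP6"} or \code{"NaCl"}.
#' @slot proteinConc numeric(1), protein concentration in micromolar.
#' @slot totalLipidConc numeric(1), total bulk lipid concentration in
#'   micromolar.
#' @slot compositionLabel character(1), liposome composition label, e.g.
#'   \code{"PM"} or \code{"PM(-)PIP2"}.
#' @exportClass TitrationCurve
setClass("TitrationCurve",
  representation(
    titrantConc = "numeric",
    fluorescence = "numeric",
    titrantKind = "character",
    proteinConc = "numeric",
    totalLipidConc = "numeric",
    compositionLabel = "character"
  ),
  prototype(
    titrantKind = "IP6",
    proteinConc = 1,
    totalLipidConc = 125,
    compositionLabel = "PM"
  )
)

setValidity("TitrationCurve", function(object) {
  msg <- NULL
  if (length(object@titrantConc) != length(object@fluorescence))
    msg <- c(msg, "titrantConc and fluorescence must have equal length")
  if (any(object@titrantConc < 0))
    msg <- c(msg, "titrant concentrations must be non-negative")
  if (length(object@titrantConc) > 1 && any(diff(object@titrantConc) <= 0))
    msg <- c(msg, "titrant concentrations must be strictly increasing")
  if (!all(is.finite(object@fluorescence)))
    msg <- c(msg, "fluorescence values must be finite")
  if (!object@titrantKind %in% c("IP6", "NaCl"))
    msg <- c(msg, "titrantKind must be 'IP6' or 'NaCl'")
  if (length(object@proteinConc) != 1 || object@proteinConc <= 0)
    msg <- c(msg, "proteinConc must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Hyperbolic competition fit result
#'
#' Parameters of the single-site competitive-inhibition model
#' F = dFmax * (1 - x / (IC50 + x)) + C fitted to a \linkS4class{TitrationCurve}.
#'
#' @slot ic50 numeric(1), half-displacement titrant concentration (same units
#'   as the curve's titrant axis, micromolar for IP6).
#' @slot deltaFmax numeric(1), total displaceable FRET amplitude.
#' @slot offset numeric(1), baseline offset C.
#' @slot stdErrors named numeric, asymptotic standard errors of the three
#'   parameters.
#' @slot rss numeric(1), residual sum of squares.
#' @slot nPoints integer(1), number of points fitted.
#' @exportClass CompetitionFit
setClass("CompetitionFit",
  representation(
    ic50 = "numeric",
    deltaFmax = "numeric",
    offset = "numeric",
    stdErrors = "numeric",
    rss = "numeric",
    nPoints = "integer"
  )
)

setValidity("CompetitionFit", function(object) {
  msg <- NULL
  if (object@ic50 <= 0) msg <- c(msg, "ic50 must be positive")
  if (object@deltaFmax < 0) msg <- c(msg, "deltaFmax must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Constants for mole-fraction partitioning calculations
#'
#' @slot ki numeric(1), protein-inhibitor dissociation constant in micromolar
#'   (default 1.8 for IP6).
#' @slot waterMolarity numeric(1), bulk water concentration in molar
#'   (default 55.5).
#' @slot accessibleLipid numeric(1), accessible (outer-leaflet) lipid
#'   concentration in micromolar.
#' @slot temperature numeric(1), absolute temperature in kelvin
#'   (default 298.15).
#' @exportClass PartitioningInputs
setClass("PartitioningInputs",
  representation(
    ki = "numeric",
    waterMolarity = "numeric",
    accessibleLipid = "numeric",
    temperature = "numeric"
  ),
  prototype(ki = 1.8, waterMolarity = 55.5, accessibleLipid = 62.5,
            temperature = 298.15)
)

setValidity("PartitioningInputs", function(object) {
  vals <- c(object@ki, object@waterMolarity, object@accessibleLipid,
            object@temperature)
  if (any(!is.finite(vals)) || any(vals <= 0))
    "all partitioning constants must be finite and strictly positive"
  else TRUE
})

#' Mole-fraction partitioning result
#'
#' @slot kx numeric(1), dimensionless mole-fraction partition coefficient.
#' @slot deltaG numeric(1), standard binding free energy in kcal/mol.
#' @slot gasConstant numeric(1), gas constant used, kcal/(mol K).
#' @slot inputs PartitioningInputs used for the conversion.
#' @exportClass PartitioningResult
setClass("PartitioningResult",
  representation(
    kx = "numeric",
    deltaG = "numeric",
    gasConstant = "numeric",
    inputs = "PartitioningInputs"
  )
)

setValidity("PartitioningResult", function(object) {
  msg <- NULL
  if (object@kx <= 0) msg <- c(msg, "kx must be positive")
  dg <- -object@gasConstant * object@inputs@temperature * log(object@kx)
  if (abs(dg - object@deltaG) > 1e-9 * max(1, abs(dg)))
    msg <- c(msg, "deltaG inconsistent with -R*T*ln(kx)")
  if (is.null(msg)) TRUE else msg
})

#' Stopped-flow kinetic trace
#'
#' @slot time numeric, time in seconds, strictly ascending.
#' @slot signal numeric, fluorescence signal (arbitrary units).
#' @slot deadTime numeric(1), instrument dead time in seconds; points at
#'   t < deadTime are excluded from fitting.
#' @slot nReplicates integer(1), number of replicate shots averaged.
#' @exportClass KineticTrace
setClass("KineticTrace",
  representation(
    time = "numeric",
    signal = "numeric",
    deadTime = "numeric",
    nReplicates = "integer"
  ),
  prototype(deadTime = 0.0014, nReplicates = 1L)
)

setValidity("KineticTrace", function(object) {
  msg <- NULL
  if (length(object@time) != length(object@signal))
    msg <- c(msg, "time and signal must have equal length")
  if (length(object@time) > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly ascending")
  if (object@deadTime < 0) msg <- c(msg, "deadTime must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Single-exponential association fit
#'
#' @slot kObs numeric(1), observed association rate constant (1/s).
#' @slot deltaFmax numeric(1), signal amplitude.
#' @slot offset numeric(1), baseline offset C.
#' @slot stdErrors named numeric, standard errors.
#' @slot rss numeric(1), residual sum of squares.
#' @exportClass AssociationFit
setClass("AssociationFit",
  representation(
    kObs = "numeric",
    deltaFmax = "numeric",
    offset = "numeric",
    stdErrors = "numeric",
    rss = "numeric"
  )
)

setValidity("AssociationFit", function(object) {
  if (object@kObs <= 0) "kObs must be positive" else TRUE
})

#' Single or double exponential dissociation fit
#'
#' Rates are stored fast-first; amplitude fractions are percentages of the
#' total amplitude and sum to 100.
#'
#' @slot model character(1), \code{"single"} or \code{"double"}.
#' @slot rates numeric, dissociation rate constants (1/s), sorted descending.
#' @slot amplitudes numeric, component amplitudes, same order as rates.
#' @slot offset numeric(1), baseline offset C.
#' @slot stdErrors named numeric, standard errors of fitted parameters.
#' @slot rss numeric(1), residual sum of squares.
#' @slot aicc named numeric, corrected Akaike information criterion per
#'   candidate model (present when model selection was run).
#' @exportClass DissociationFit
setClass("DissociationFit",
  representation(
    model = "character",
    rates = "numeric",
    amplitudes = "numeric",
    offset = "numeric",
    stdErrors = "numeric",
    rss = "numeric",
    aicc = "numeric"
  )
)

setValidity("DissociationFit", function(object) {
  msg <- NULL
  if (!object@model %in% c("single", "double"))
    msg <- c(msg, "model must be 'single' or 'double'")
  if (any(object@rates <= 0)) msg <- c(msg, "all rates must be positive")
  if (length(object@rates) != length(object@amplitudes))
    msg <- c(msg, "rates and amplitudes must have equal length")
  if (length(object@rates) > 1 && any(diff(object@rates) >= 0))
    msg <- c(msg, "rates must be sorted descending (fast first)")
  if (is.null(msg)) TRUE else msg
})

#' Mole-fraction association rate constant
#'
#' @slot konX numeric(1), mole-fraction association rate constant (1/s).
#' @slot kObs numeric(1), observed association rate (1/s).
#' @slot kOff numeric(1), dissociation rate subtracted (1/s).
#' @slot inputs PartitioningInputs used (water molarity, accessible lipid).
#' @exportClass RateResult
setClass("RateResult",
  representation(
    konX = "numeric",
    kObs = "numeric",
    kOff = "numeric",
    inputs = "PartitioningInputs"
  )
)

setValidity("RateResult", function(object) {
  if (object@konX <= 0) "konX must be positive" else TRUE
})

#' Coordinate frame of a membrane-protein system
#'
#' Typed atom records for one snapshot: protein residues plus lipid
#' molecules, with Cartesian coordinates in angstroms and atomic masses.
#' Lipid molecules are identified by the combination of segment/chain and
#' residue number.
#'
#' @slot atoms data.frame with columns \code{atom} (atom name), \code{element},
#'   \code{resname}, \code{resno} (integer), \code{segid}, \code{x}, \code{y},
#'   \code{z} (angstrom), \code{mass} (amu).
#' @slot box numeric, either length 3 (Lx, Ly, Lz in angstrom) or length 0
#'   when no periodic box is defined.
#' @slot time numeric(1), frame time in nanoseconds.
#' @exportClass MembraneFrame
setClass("MembraneFrame",
  representation(
    atoms = "data.frame",
    box = "numeric",
    time = "numeric"
  ),
  prototype(box = numeric(0), time = 0)
)

setValidity("MembraneFrame", function(object) {
  msg <- NULL
  need <- c("atom", "element", "resname", "resno", "segid",
            "x", "y", "z", "mass")
  missing <- setdiff(need, names(object@atoms))
  if (length(missing))
    msg <- c(msg, paste("atoms is missing columns:",
                        paste(missing, collapse = ", ")))
  else {
    if (!all(is.finite(object@atoms$x)) || !all(is.finite(object@atoms$y)) ||
        !all(is.finite(object@atoms$z)))
      msg <- c(msg, "coordinates must be finite")
    if (any(object@atoms$mass <= 0))
      msg <- c(msg, "atom masses must be positive")
  }
  if (length(object@box) > 0 &&
      (length(object@box) != 3 || any(object@box <= 0)))
    msg <- c(msg, "box must be empty or three positive lengths")
  if (is.null(msg)) TRUE else msg
})

#' Multi-frame trajectory
#'
#' An ordered list of \linkS4class{MembraneFrame} snapshots.
#'
#' @slot frames list of MembraneFrame.
#' @exportClass MembraneTrajectory
setClass("MembraneTrajectory", representation(frames = "list"))

setValidity("MembraneTrajectory", function(object) {
  if (!all(vapply(object@frames, is, logical(1), "MembraneFrame")))
    "all elements must be MembraneFrame objects"
  else TRUE
})

#' Loop tip definition
#'
#' A named loop whose tip is the center of mass of the C-alpha atoms of three
#' consecutive residues.
#'
#' @slot name character(1), loop name, e.g. \code{"beta2-beta3"}.
#' @slot tipResidues integer(3), residue numbers of the three tip residues.
#' @exportClass LoopDefinition
setClass("LoopDefinition",
  representation(name = "character", tipResidues = "integer"))

setValidity("LoopDefinition", function(object) {
  if (length(object@tipResidues) != 3)
    "tipResidues must contain exactly three residue numbers"
  else TRUE
})

#' Per-frame, per-residue, per-lipid-type contact counts
#'
#' @slot counts 3-d integer array with dimensions
#'   (frame, residue, lipid type) and dimnames; entry (f, r, t) is the number
#'   of distinct lipid molecules of type t contacted by residue r in frame f.
#' @slot times numeric, frame times in nanoseconds (one per frame).
#' @exportClass ContactSeries
setClass("ContactSeries",
  representation(counts = "array", times = "numeric"))

setValidity("ContactSeries", function(object) {
  msg <- NULL
  if (length(dim(object@counts)) != 3)
    msg <- c(msg, "counts must be a 3-d array (frame x residue x lipid type)")
  else if (dim(object@counts)[1] != length(object@times))
    msg <- c(msg, "first dimension of counts must match length(times)")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Set of docked ligand reference positions
#'
#' One reference point (e.g. ligand heavy-atom centroid) per docking run.
#'
#' @slot positions numeric matrix, n x 3, columns x/y/z in angstroms.
#' @slot runLabels character, optional identifiers (length n or 0).
#' @exportClass PoseSet
setClass("PoseSet",
  representation(positions = "matrix", runLabels = "character"),
  prototype(runLabels = character(0)))

setValidity("PoseSet", function(object) {
  msg <- NULL
  if (ncol(object@positions) != 3) msg <- c(msg, "positions must be n x 3")
  if (nrow(object@positions) < 1) msg <- c(msg, "at least one pose required")
  if (!all(is.finite(object@positions)))
    msg <- c(msg, "pose coordinates must be finite")
  if (length(object@runLabels) &&
      length(object@runLabels) != nrow(object@positions))
    msg <- c(msg, "runLabels must be empty or one per pose")
  if (is.null(msg)) TRUE else msg
})

#' Named binding site definition
#'
#' The site center is the center of mass of the anchor atoms of the listed
#' residues (NZ for Lys, CZ for Arg, imidazole-ring center for His, C-alpha
#' otherwise).
#'
#' @slot name character(1).
#' @slot anchorResidues integer, residue numbers defining the site.
#' @exportClass SiteDefinition
setClass("SiteDefinition",
  representation(name = "character", anchorResidues = "integer"))

setValidity("SiteDefinition", function(object) {
  if (length(object@anchorResidues) < 1)
    "at least one anchor residue required"
  else TRUE
})

#' Post-translational modification specification
#'
#' @slot name character(1), e.g. \code{"phosphogluconoyl"}.
#' @slot composition named integer vector, element -> count (net atoms added).
#' @slot targetResidues character, single-letter codes of modifiable residues.
#' @slot fixed logical(1), fixed (always applied) vs variable modification.
#' @exportClass ModificationSpec
setClass("ModificationSpec",
  representation(
    name = "character",
    composition = "integer",
    targetResidues = "character",
    fixed = "logical"
  ),
  prototype(fixed = FALSE))

setValidity("ModificationSpec", function(object) {
  msg <- NULL
  if (length(object@composition) == 0)
    msg <- c(msg, "composition must be non-empty")
  if (any(object@composition < 0))
    msg <- c(msg, "element counts must be non-negative")
  if (length(object@composition) && all(object@composition == 0))
    msg <- c(msg, "composition must not be all zero")
  if (is.null(names(object@composition)) ||
      any(!nzchar(names(object@composition))))
    msg <- c(msg, "composition must be a named element -> count vector")
  if (is.null(msg)) TRUE else msg
})

#' Peptide with site-specific modifications
#'
#' @slot sequence character(1), one-letter residue codes (uppercase).
#' @slot siteModifications list mapping position (as stored in
#'   \code{names()}, coercible to integer) to \linkS4class{ModificationSpec}.
#' @exportClass ModifiedPeptide
setClass("ModifiedPeptide",
  representation(sequence = "character", siteModifications = "list"),
  prototype(siteModifications = list()))

setValidity("ModifiedPeptide", function(object) {
  msg <- NULL
  seqchars <- strsplit(object@sequence, "")[[1]]
  if (length(object@siteModifications)) {
    pos <- as.integer(names(object@siteModifications))
    if (any(is.na(pos)) || any(pos < 1) || any(pos > length(seqchars)))
      msg <- c(msg, "modification positions must lie within the sequence")
    else {
      for (i in seq_along(pos)) {
        spec <- object@siteModifications[[i]]
        if (!is(spec, "ModificationSpec"))
          msg <- c(msg, "siteModifications must contain ModificationSpec")
        else if (length(spec@targetResidues) &&
                 !seqchars[pos[i]] %in% spec@targetResidues)
          msg <- c(msg, sprintf(
            "residue %s at position %d is not a target of modification '%s'",
            seqchars[pos[i]], pos[i], spec@name))
      }
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Mass tolerance policy
#'
#' @slot precursorPpm numeric(1), precursor match tolerance in ppm
#'   (default 20).
#' @slot fragmentPpm numeric(1), fragment match tolerance in ppm (default 50).
#' @slot intactDa numeric(1), intact-protein mass-shift tolerance in daltons
#'   (default 1.0).
#' @exportClass TolerancePolicy
setClass("TolerancePolicy",
  representation(precursorPpm = "numeric", fragmentPpm = "numeric",
                 intactDa = "numeric"),
  prototype(precursorPpm = 20, fragmentPpm = 50, intactDa = 1.0))

setValidity("TolerancePolicy", function(object) {
  if (any(c(object@precursorPpm, object@fragmentPpm, object@intactDa) <= 0))
    "all tolerances must be positive"
  else TRUE
})
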