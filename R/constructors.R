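#' Construct a titration curve
#'
#' @param titrantConc numeric vector of titrant concentrations
#'   (micromolar for IP6, millimolar allowed for NaCl), strictly increasing.
#' @param fluorescence numeric vector of fluorescence intensities.
#' @param titrantKind \code{"IP6"} or \code{"NaCl"}.
#' @param proteinConc protein concentration in micromolar.
#' @param totalLipidConc total bulk lipid concentration in micromolar.
#' @param compositionLabel liposome composition label.
#' @return A \linkS4class{TitrationCurve}.
#' @examples
#' tc <- TitrationCurve(c(0, 10, 100, 1000), c(1.0, 0.9, 0.5, 0.1))
#' titrantConc(tc)
#' @export
TitrationCurve <- function(titrantConc, fluorescence, titrantKind = "IP6",
                           proteinConc = 1, totalLipidConc = 125,
                           compositionLabel = "PM") {
  new("TitrationCurve",
      titrantConc = as.numeric(titrantConc),
      fluorescence = as.numeric(fluorescence),
      titrantKind = titrantKind,
      proteinConc = proteinConc,
      totalLipidConc = totalLipidConc,
      compositionLabel = compositionLabel)
}

#' Construct partitioning constants
#'
#' Defaults follow the competition-FRET assay conditions: inhibitor
#' dissociation constant 1.8 micromolar, bulk water 55.5 M, accessible lipid
#' 62.5 micromolar (half of 125 micromolar total), 25 degrees C.
#'
#' @param ki protein-inhibitor dissociation constant, micromolar.
#' @param waterMolarity bulk water concentration, molar.
#' @param accessibleLipid accessible lipid concentration, micromolar.
#' @param temperature absolute temperature, kelvin.
#' @return A \linkS4class{PartitioningInputs}.
#' @export
PartitioningInputs <- function(ki = 1.8, waterMolarity = 55.5,
                               accessibleLipid = 62.5,
                               temperature = 298.15) {
  new("PartitioningInputs", ki = ki, waterMolarity = waterMolarity,
      accessibleLipid = accessibleLipid, temperature = temperature)
}

#' Construct a kinetic trace
#'
#' @param time numeric, seconds, strictly ascending.
#' @param signal numeric, fluorescence signal.
#' @param deadTime instrument dead time in seconds (default 1.4 ms).
#' @param nReplicates number of replicate shots averaged into this trace.
#' @return A \linkS4class{KineticTrace}.
#' @export
KineticTrace <- function(time, signal, deadTime = 0.0014, nReplicates = 1L) {
  new("KineticTrace", time = as.numeric(time), signal = as.numeric(signal),
      deadTime = deadTime, nReplicates = as.integer(nReplicates))
}

#' Construct a coordinate frame
#'
#' @param atoms data.frame with columns atom, element, resname, resno, segid,
#'   x, y, z, mass. Missing \code{element} or \code{mass} columns are filled
#'   by inference from atom names.
#' @param box numeric(3) periodic box lengths in angstrom, or NULL.
#' @param time frame time in nanoseconds.
#' @return A \linkS4class{MembraneFrame}.
#' @export
MembraneFrame <- function(atoms, box = NULL, time = 0) {
  if (is.null(atoms$element)) atoms$element <- inferElement(atoms$atom)
  if (is.null(atoms$mass)) atoms$mass <- elementMass(atoms$element)
  if (is.null(atoms$segid)) atoms$segid <- ""
  atoms$resno <- as.integer(atoms$resno)
  new("MembraneFrame", atoms = atoms,
      box = if (is.null(box)) numeric(0) else as.numeric(box),
      time = time)
}

#' Construct a trajectory from frames
#'
#' @param frames list of \linkS4class{MembraneFrame}.
#' @return A \linkS4class{MembraneTrajectory}.
#' @export
MembraneTrajectory <- function(frames) {
  new("MembraneTrajectory", frames = frames)
}

#' Construct a loop definition
#'
#' @param name loop name.
#' @param tipResidues three consecutive residue numbers whose C-alpha
#'   centroid defines the loop tip.
#' @return A \linkS4class{LoopDefinition}.
#' @export
LoopDefinition <- function(name, tipResidues) {
  new("LoopDefinition", name = name, tipResidues = as.integer(tipResidues))
}

#' Construct a pose set
#'
#' @param positions n x 3 numeric matrix of ligand reference points
#'   (angstrom).
#' @param runLabels optional identifiers, one per pose.
#' @return A \linkS4class{PoseSet}.
#' @export
PoseSet <- function(positions, runLabels = character(0)) {
  positions <- as.matrix(positions)
  colnames(positions) <- c("x", "y", "z")
  new("PoseSet", positions = positions, runLabels = as.character(runLabels))
}

#' Construct a binding-site definition
#'
#' @param name site name, e.g. \code{"lysine_cluster"}.
#' @param anchorResidues residue numbers whose anchor atoms define the site
#'   center.
#' @return A \linkS4class{SiteDefinition}.
#' @export
SiteDefinition <- function(name, anchorResidues) {
  new("SiteDefinition", name = name,
      anchorResidues = as.integer(anchorResidues))
}

#' Construct a modification specification
#'
#' @param name modification name.
#' @param composition named integer vector of net atoms added,
#'   e.g. \code{c(C = 6, H = 11, O = 9, P = 1)}.
#' @param targetResidues single-letter codes of modifiable residues.
#' @param fixed logical, fixed vs variable modification.
#' @return A \linkS4class{ModificationSpec}.
#' @examples
#' ModificationSpec("phospho", c(H = 1, P = 1, O = 3), "STY")
#' @export
ModificationSpec <- function(name, composition, targetResidues = character(0),
                             fixed = FALSE) {
  comp <- as.integer(composition)
  names(comp) <- names(composition)
  targets <- as.character(unlist(strsplit(targetResidues, "")))
  new("ModificationSpec", name = name, composition = comp,
      targetResidues = targets, fixed = fixed)
}

#' Construct a modified peptide
#'
#' Lowercase letters in \code{sequence} mark modified sites; each lowercase
#' letter is looked up (as its uppercase residue) in \code{mods}, a named list
#' of \linkS4class{ModificationSpec} keyed by the lowercase letter used.
#' Alternatively pass explicit \code{siteModifications}.
#'
#' @param sequence peptide sequence; lowercase letters mark modified sites.
#' @param mods named list, lowercase letter -> ModificationSpec.
#' @param siteModifications explicit list, names are positions.
#' @return A \linkS4class{ModifiedPeptide}.
#' @examples
#' pg <- ModificationSpec("phosphogluconoyl", c(C = 6, H = 11, O = 9, P = 1), "K")
#' pep <- ModifiedPeptide("SNPYVkTYLLPD", mods = list(k = pg))
#' @export
ModifiedPeptide <- function(sequence, mods = list(),
                            siteModifications = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  if (is.null(siteModifications)) {
    siteModifications <- list()
    lower <- which(chars %in% letters)
    for (p in lower) {
      key <- chars[p]
      if (!key %in% names(mods))
        stop("no modification supplied for lowercase letter '", key, "'")
      siteModifications[[as.character(p)]] <- mods[[key]]
    }
  }
  new("ModifiedPeptide", sequence = toupper(sequence),
      siteModifications = siteModifications)
}

#' Construct a tolerance policy
#'
#' @param precursorPpm precursor tolerance, ppm (default 20).
#' @param fragmentPpm fragment tolerance, ppm (default 50).
#' @param intactDa intact-protein mass-shift tolerance, Da (default 1.0).
#' @return A \linkS4class{TolerancePolicy}.
#' @export
TolerancePolicy <- function(precursorPpm = 20, fragmentPpm = 50,
                            intactDa = 1.0) {
  new("TolerancePolicy", precursorPpm = precursorPpm,
      fragmentPpm = fragmentPpm, intactDa = intactDa)
}
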