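# atomic masses (amu) for elements occurring in proteins and phospholipids
.ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06, K = 39.098, CL = 35.45,
                     NA. = 22.990, MG = 24.305, CA. = 40.078, FE = 55.845)

# three-letter protein residue names, including CHARMM histidine tautomers
.PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP")

.HIS_RESNAMES <- c("HIS", "HSD", "HSE", "HSP")
.HIS_RING_ATOMS <- c("CG", "ND1", "CD2", "CE1", "NE2")

.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", HSD = "H", HSE = "H", HSP = "H",
          ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Infer the chemical element from an atom name
#'
#' Used when the PDB element column (77-78) is empty. Leading digits are
#' stripped and the first alphabetic character is taken, which resolves
#' standard protein/lipid atom names (NZ -> N, CZ -> C, O13 -> O, P4 -> P,
#' 1HB -> H).
#'
#' @param atomName character vector of atom names.
#' @return character vector of element symbols.
#' @export
inferElement <- function(atomName) {
  core <- sub("^[0-9' ]+", "", trimws(atomName))
  toupper(substr(core, 1, 1))
}

#' Atomic mass lookup
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @export
elementMass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  key[key == "CA"] <- "CA."
  m <- .ELEMENT_MASSES[key]
  if (any(is.na(m)))
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

# logical mask of protein atoms in a frame
.isProtein <- function(frame) {
  frame@atoms$resname %in% .PROTEIN_RESNAMES
}

# molecule identity for lipids: segment + residue number
.moleculeId <- function(atomsDf) {
  paste(atomsDf$segid, atomsDf$resno, sep = ":")
}

#' Read coordinate frames from a (possibly multi-model) PDB file
#'
#' Parses ATOM/HETATM records via \code{bio3d::read.pdb}; MODEL/ENDMDL blocks
#' become successive frames and a CRYST1 record supplies the periodic box.
#' Elements missing from columns 77-78 are inferred from atom names, and
#' atomic masses are assigned from the element.
#'
#' @param path path to a PDB file.
#' @param times optional numeric vector of frame times in nanoseconds
#'   (defaults to 0, 1, 2, ...).
#' @return A \linkS4class{MembraneTrajectory}.
#' @export
readMembraneFrames <- function(path, times = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | !nzchar(trimws(elem))))
    elem <- inferElement(at$elety)
  else {
    elem <- trimws(elem)
    blank <- is.na(elem) | !nzchar(elem)
    elem[blank] <- inferElement(at$elety[blank])
  }
  box <- numeric(0)
  cryst <- grep("^CRYST1", readLines(path, n = 50), value = TRUE)
  if (length(cryst)) {
    abc <- suppressWarnings(as.numeric(c(
      substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
      substr(cryst[1], 25, 33))))
    if (all(is.finite(abc)) && all(abc > 0)) box <- abc
  }
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  nFrames <- nrow(xyz)
  if (is.null(times)) times <- seq_len(nFrames) - 1
  segid <- at$segid
  if (is.null(segid) || all(is.na(segid) | !nzchar(trimws(segid))))
    segid <- ifelse(is.na(at$chain), "", at$chain)
  segid[is.na(segid)] <- ""
  frames <- vector("list", nFrames)
  for (i in seq_len(nFrames)) {
    co <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    frames[[i]] <- MembraneFrame(
      data.frame(atom = trimws(at$elety), element = elem,
                 resname = trimws(at$resid), resno = at$resno,
                 segid = trimws(segid),
                 x = co[, 1], y = co[, 2], z = co[, 3],
                 mass = elementMass(elem),
                 stringsAsFactors = FALSE),
      box = if (length(box)) box else NULL,
      time = times[i])
  }
  MembraneTrajectory(frames)
}

#' Write frames to a multi-model PDB file
#'
#' Writes standard fixed-width ATOM records, one MODEL/ENDMDL block per
#' frame, with a CRYST1 record when the first frame carries a box. The
#' output is readable by \code{\link{readMembraneFrames}} and standard
#' structure viewers.
#'
#' @param trajectory a \linkS4class{MembraneTrajectory} or single
#'   \linkS4class{MembraneFrame}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeMembraneFrames <- function(trajectory, path) {
  if (is(trajectory, "MembraneFrame"))
    trajectory <- MembraneTrajectory(list(trajectory))
  con <- file(path, "w")
  on.exit(close(con))
  f1 <- trajectory@frames[[1]]
  if (length(f1@box) == 3)
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      f1@box[1], f1@box[2], f1@box[3], 90, 90, 90), con)
  multi <- length(trajectory@frames) > 1
  for (i in seq_along(trajectory@frames)) {
    fr <- trajectory@frames[[i]]
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    a <- fr@atoms
    serial <- seq_len(nrow(a)) %% 100000
    lines <- sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
      serial, substr(a$atom, 1, 4), substr(a$resname, 1, 4),
      ifelse(nzchar(a$segid), substr(a$segid, 1, 1), "A"),
      a$resno %% 10000, a$x, a$y, a$z, 1, 0,
      substr(a$segid, 1, 4), substr(a$element, 1, 2))
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
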