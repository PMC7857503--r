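#' Default electrostatic contact criteria
#'
#' Anchor definitions and distance cutoffs per basic-residue class: lysine
#' amine nitrogen NZ at 5.0 angstrom, arginine guanidino carbon CZ at 6.3
#' angstrom, histidine imidazole-ring heavy-atom center of mass (CG, ND1,
#' CD2, CE1, NE2) at 6.1 angstrom. Histidine tautomer names (HSD/HSE/HSP)
#' are treated as histidine.
#'
#' @return Named list with one entry per residue class, each holding
#'   \code{anchor} (atom name or \code{"ring_com"}) and \code{cutoff}
#'   (angstrom).
#' @export
contactCriteria <- function() {
  list(
    LYS = list(anchor = "NZ", cutoff = 5.0),
    ARG = list(anchor = "CZ", cutoff = 6.3),
    HIS = list(anchor = "ring_com", cutoff = 6.1)
  )
}

#' Default lipid headgroup heavy-atom specification
#'
#' Heavy-atom names counted as "headgroup" per lipid type, using CHARMM36
#' atom naming: for the anionic lipids (PS, PIP2) the atoms from the
#' phosphodiester linkage outward; for PC the atoms from the glycerol
#' backbone outward. Atom naming is force-field dependent, so both the atom
#' lists and the residue-name-to-type map are fully overrideable.
#'
#' @return List with \code{atoms} (named list, lipid type -> atom-name
#'   vector) and \code{resnameMap} (named character, residue name -> lipid
#'   type).
#' @export
headgroupSpec <- function() {
  list(
    atoms = list(
      PC = c("C1", "C2", "C3", "O21", "O31", "P", "O11", "O12", "O13",
             "O14", "C11", "C12", "C13", "C14", "C15", "N"),
      PS = c("P", "O11", "O12", "O13", "O14", "C11", "C12", "C13",
             "N", "O13A", "O13B"),
      PIP2 = c("P", "O11", "O12", "O13", "O14",
               "C11", "C12", "C13", "C14", "C15", "C16",
               "O2", "O3", "O4", "O5", "O6",
               "P4", "OP42", "OP43", "OP44",
               "P5", "OP52", "OP53", "OP54")
    ),
    resnameMap = c(POPC = "PC", DPPC = "PC", PC = "PC",
                   POPS = "PS", DOPS = "PS", PS = "PS",
                   SAPI = "PIP2", SAP2 = "PIP2", SAPI24 = "PIP2",
                   SAPI25 = "PIP2", PIP2 = "PIP2")
  )
}

#' Loop-tip definitions of the C2A domain
#'
#' The three membrane-proximal loops whose tips are tracked: beta2-beta3
#' (E388/A389/K390), beta6-beta7 (G450/R451/F452) and beta3-beta4
#' (S406/R407/Q408).
#'
#' @return Named list of \linkS4class{LoopDefinition}.
#' @export
c2aLoopDefinitions <- function() {
  list(
    "beta2-beta3" = LoopDefinition("beta2-beta3", 388:390),
    "beta6-beta7" = LoopDefinition("beta6-beta7", 450:452),
    "beta3-beta4" = LoopDefinition("beta3-beta4", 406:408)
  )
}

# lipid phosphorus atoms: element P in non-protein residues
.lipidPhosphorus <- function(frame) {
  a <- frame@atoms
  a[a$element == "P" & !(a$resname %in% .PROTEIN_RESNAMES) &
      a$atom == "P", , drop = FALSE]
}

#' Average z of the phosphate plane
#'
#' Unweighted mean z-coordinate of the lipid phosphodiester phosphorus atoms
#' in the selected leaflet. Leaflet assignment: phosphorus atoms with z above
#' the mean of all lipid phosphorus z form the upper leaflet; the
#' protein-facing leaflet is the one whose mean phosphorus z is nearer the
#' protein center of mass.
#'
#' @param frame a \linkS4class{MembraneFrame}.
#' @param leaflet \code{"protein_facing"}, \code{"upper"} or \code{"lower"}.
#' @return z of the phosphate plane in angstrom.
#' @export
phosphatePlaneZ <- function(frame,
                            leaflet = c("protein_facing", "upper", "lower")) {
  leaflet <- match.arg(leaflet)
  p <- .lipidPhosphorus(frame)
  if (!nrow(p)) stop("missing selection: no lipid phosphorus atoms in frame")
  mid <- mean(p$z)
  upper <- p$z >= mid
  zUpper <- p$z[upper]
  zLower <- p$z[!upper]
  if (leaflet == "protein_facing") {
    com <- proteinCenterOfMass(frame)
    mUp <- if (length(zUpper)) mean(zUpper) else -Inf
    mLo <- if (length(zLower)) mean(zLower) else Inf
    sel <- if (abs(com[3] - mUp) <= abs(com[3] - mLo)) zUpper else zLower
  } else if (leaflet == "upper") sel <- zUpper else sel <- zLower
  if (!length(sel))
    stop("missing selection: no phosphorus atoms in the requested leaflet")
  mean(sel)
}

#' Mass-weighted protein center of mass
#'
#' @param frame a \linkS4class{MembraneFrame}.
#' @param atomSubset \code{"all"} (default) or \code{"calpha"} to restrict to
#'   C-alpha atoms.
#' @return numeric(3), (x, y, z) in angstrom.
#' @export
proteinCenterOfMass <- function(frame, atomSubset = c("all", "calpha")) {
  atomSubset <- match.arg(atomSubset)
  a <- frame@atoms[.isProtein(frame), , drop = FALSE]
  if (atomSubset == "calpha") a <- a[a$atom == "CA", , drop = FALSE]
  if (!nrow(a)) stop("missing selection: no protein atoms in frame")
  w <- a$mass / sum(a$mass)
  c(sum(w * a$x), sum(w * a$y), sum(w * a$z))
}

#' Height of the protein center of mass above the phosphate plane
#'
#' @param frame a \linkS4class{MembraneFrame}.
#' @param planeZ z of the phosphate plane (angstrom); computed from the
#'   protein-facing leaflet when NULL.
#' @return Height in angstrom (positive above the plane).
#' @export
proteinComHeight <- function(frame, planeZ = NULL) {
  if (is.null(planeZ)) planeZ <- phosphatePlaneZ(frame, "protein_facing")
  proteinCenterOfMass(frame)[3] - planeZ
}

#' Insertion depth of a residue relative to the phosphate plane
#'
#' z of the representative atom minus the plane z; negative values indicate
#' insertion below the phosphate plane.
#'
#' @param frame a \linkS4class{MembraneFrame}.
#' @param residueNumber residue number.
#' @param representation \code{"c_alpha"} (default) or \code{"named_atom"}.
#' @param atomName atom name when \code{representation = "named_atom"}.
#' @param planeZ z of the phosphate plane; computed from the protein-facing
#'   leaflet when NULL.
#' @return Depth in angstrom.
#' @export
residueDepth <- function(frame, residueNumber,
                         representation = c("c_alpha", "named_atom"),
                         atomName = NULL, planeZ = NULL) {
  representation <- match.arg(representation)
  if (is.null(planeZ)) planeZ <- phosphatePlaneZ(frame, "protein_facing")
  a <- frame@atoms[.isProtein(frame), , drop = FALSE]
  a <- a[a$resno == residueNumber, , drop = FALSE]
  want <- if (representation == "c_alpha") "CA" else atomName
  if (is.null(want)) stop("atomName required for representation 'named_atom'")
  hit <- a[a$atom == want, , drop = FALSE]
  if (!nrow(hit))
    stop("missing atom: no '", want, "' in residue ", residueNumber)
  hit$z[1] - planeZ
}

#' Loop tip position
#'
#' Mass-weighted center of mass of the C-alpha atoms of the three tip
#' residues (equal masses, so the centroid).
#'
#' @param frame a \linkS4class{MembraneFrame}.
#' @param loop a \linkS4class{LoopDefinition}.
#' @return numeric(3), (x, y, z) in angstrom.
#' @export
loopTipPosition <- function(frame, loop) {
  stopifnot(is(loop, "LoopDefinition"))
  a <- frame@atoms[.isProtein(frame), , drop = FALSE]
  ca <- a[a$atom == "CA" & a$resno %in% loop@tipResidues, , drop = FALSE]
  if (nrow(ca) != 3)
    stop("missing atom: expected 3 C-alpha atoms for loop '", loop@name,
         "', found ", nrow(ca))
  w <- ca$mass / sum(ca$mass)
  c(sum(w * ca$x), sum(w * ca$y), sum(w * ca$z))
}

#' Angle between two loop tips at the protein center of mass
#'
#' The angle at the protein COM between the vectors COM -> tip_a and
#' COM -> tip_b, in degrees within [0, 180].
#'
#' @param frame a \linkS4class{MembraneFrame}.
#' @param loopA,loopB \linkS4class{LoopDefinition} objects.
#' @param comAtoms atom subset for the protein COM (\code{"all"} or
#'   \code{"calpha"}).
#' @return Angle in degrees.
#' @export
interloopAngle <- function(frame, loopA, loopB, comAtoms = "all") {
  com <- proteinCenterOfMass(frame, comAtoms)
  va <- loopTipPosition(frame, loopA) - com
  vb <- loopTipPosition(frame, loopB) - com
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na < 1e-9 || nb < 1e-9)
    stop("degenerate geometry: zero-length COM-to-tip vector")
  cosang <- sum(va * vb) / (na * nb)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# squared distances from one point to a coordinate matrix, minimum-image in
# x-y when a box is present (z treated as non-periodic, the bilayer normal)
.sqDistTo <- function(point, xyz, box) {
  dx <- xyz[, 1] - point[1]
  dy <- xyz[, 2] - point[2]
  dz <- xyz[, 3] - point[3]
  if (length(box) == 3) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
  }
  dx * dx + dy * dy + dz * dz
}

# anchor points of the basic residues in a frame: one row per LYS/ARG/HIS
.basicAnchors <- function(frame, criteria) {
  a <- frame@atoms[.isProtein(frame), , drop = FALSE]
  out <- list()
  for (cls in names(criteria)) {
    resnames <- switch(cls, HIS = .HIS_RESNAMES, cls)
    sub <- a[a$resname %in% resnames, , drop = FALSE]
    if (!nrow(sub)) next
    for (rn in unique(sub$resno)) {
      res <- sub[sub$resno == rn, , drop = FALSE]
      anchor <- criteria[[cls]]$anchor
      if (identical(anchor, "ring_com")) {
        ring <- res[res$atom %in% .HIS_RING_ATOMS, , drop = FALSE]
        if (!nrow(ring)) next
        w <- ring$mass / sum(ring$mass)
        pt <- c(sum(w * ring$x), sum(w * ring$y), sum(w * ring$z))
      } else {
        hit <- res[res$atom == anchor, , drop = FALSE]
        if (!nrow(hit)) next
        pt <- c(hit$x[1], hit$y[1], hit$z[1])
      }
      label <- paste0(.AA1[[res$resname[1]]], rn)
      out[[label]] <- list(label = label, cutoff = criteria[[cls]]$cutoff,
                           point = pt)
    }
  }
  out
}

#' Per-residue electrostatic lipid contacts in one frame
#'
#' For each basic residue (Lys/Arg/His), counts the number of distinct lipid
#' molecules of each type with at least one headgroup heavy atom within the
#' residue-class cutoff of the residue anchor. A lipid contacted through
#' several atoms counts once. Distances use the minimum-image convention in
#' x-y when the frame has a box.
#'
#' @param frame a \linkS4class{MembraneFrame}.
#' @param criteria contact criteria, see \code{\link{contactCriteria}}.
#' @param headgroups headgroup specification, see \code{\link{headgroupSpec}}.
#' @return Integer matrix, rows = basic residues (e.g. "K390"), columns =
#'   lipid types.
#' @export
lipidContacts <- function(frame, criteria = contactCriteria(),
                          headgroups = headgroupSpec()) {
  a <- frame@atoms
  lipid <- a[!(a$resname %in% .PROTEIN_RESNAMES), , drop = FALSE]
  lipid <- lipid[lipid$element != "H", , drop = FALSE]
  unknown <- setdiff(unique(lipid$resname), names(headgroups$resnameMap))
  if (length(unknown))
    stop("configuration error: lipid residue name(s) not in headgroup spec: ",
         paste(unknown, collapse = ", "))
  types <- sort(unique(unname(headgroups$resnameMap[lipid$resname])))
  anchors <- .basicAnchors(frame, criteria)
  counts <- matrix(0L, nrow = length(anchors), ncol = length(types),
                   dimnames = list(names(anchors), types))
  if (!nrow(lipid) || !length(anchors)) return(counts)
  lipid$type <- unname(headgroups$resnameMap[lipid$resname])
  lipid$mol <- .moleculeId(lipid)
  # keep only declared headgroup atoms, per type
  keep <- logical(nrow(lipid))
  for (tp in types) {
    sel <- lipid$type == tp & lipid$atom %in% headgroups$atoms[[tp]]
    keep <- keep | sel
  }
  lipid <- lipid[keep, , drop = FALSE]
  xyz <- as.matrix(lipid[, c("x", "y", "z")])
  for (an in anchors) {
    d2 <- .sqDistTo(an$point, xyz, frame@box)
    hit <- d2 <= an$cutoff^2
    if (any(hit)) {
      tab <- tapply(lipid$mol[hit], lipid$type[hit],
                    function(m) length(unique(m)))
      counts[an$label, names(tab)] <- as.integer(tab)
    }
  }
  counts
}

#' Contact counts across a trajectory
#'
#' Applies \code{\link{lipidContacts}} to every frame and assembles a
#' \linkS4class{ContactSeries} (frame x residue x lipid type).
#'
#' @param trajectory a \linkS4class{MembraneTrajectory}.
#' @param criteria contact criteria, see \code{\link{contactCriteria}}.
#' @param headgroups headgroup specification, see \code{\link{headgroupSpec}}.
#' @return A \linkS4class{ContactSeries}.
#' @export
lipidContactSeries <- function(trajectory, criteria = contactCriteria(),
                               headgroups = headgroupSpec()) {
  stopifnot(is(trajectory, "MembraneTrajectory"))
  per <- lapply(trajectory@frames, lipidContacts, criteria = criteria,
                headgroups = headgroups)
  resnames <- rownames(per[[1]])
  types <- colnames(per[[1]])
  arr <- array(0L, dim = c(length(per), length(resnames), length(types)),
               dimnames = list(NULL, resnames, types))
  for (i in seq_along(per)) {
    m <- per[[i]]
    arr[i, rownames(m), colnames(m)] <- m
  }
  new("ContactSeries", counts = arr, times = frameTimes(trajectory))
}

#' Windowed contact statistics
#'
#' Mean and standard deviation of contact counts per residue and lipid type
#' over a time window: either the trailing fraction of the trajectory
#' (e.g. the last half, emulating averaging over the last 100 ns of a 200-ns
#' run) or an explicit time range in nanoseconds. The SD is computed across
#' the saved frames in the window.
#'
#' @param series a \linkS4class{ContactSeries}.
#' @param window either \code{list(lastFraction = f)} with f in (0, 1], or
#'   \code{c(tmin, tmax)} in nanoseconds.
#' @return data.frame with columns residue, lipidType, mean, sd, nFrames.
#' @export
contactTimeStatistics <- function(series,
                                  window = list(lastFraction = 0.5)) {
  stopifnot(is(series, "ContactSeries"))
  tt <- series@times
  if (is.list(window)) {
    f <- window$lastFraction
    stopifnot(is.numeric(f), f > 0, f <= 1)
    tmin <- max(tt) - f * (max(tt) - min(tt))
    keep <- tt >= tmin - 1e-9
  } else {
    keep <- tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9
  }
  if (!any(keep)) stop("empty window: no frames in the requested range")
  sub <- series@counts[keep, , , drop = FALSE]
  res <- dimnames(sub)[[2]]
  types <- dimnames(sub)[[3]]
  grid <- expand.grid(residue = res, lipidType = types,
                      stringsAsFactors = FALSE)
  grid$mean <- mapply(function(r, tp) mean(sub[, r, tp]),
                      grid$residue, grid$lipidType)
  grid$sd <- mapply(function(r, tp) stats::sd(sub[, r, tp]),
                    grid$residue, grid$lipidType)
  if (dim(sub)[1] == 1) grid$sd <- 0
  grid$nFrames <- sum(keep)
  grid
}

#' Per-frame totals of basic residues in contact
#'
#' For each frame and lipid type, the number of distinct basic residues with
#' at least one lipid contact of that type (residues, not contacts). The
#' result is a \linkS4class{ContactSeries} with a single pseudo-residue
#' \code{"basic_total"}, so \code{\link{contactTimeStatistics}} applies
#' unchanged for windowed summaries.
#'
#' @param series a \linkS4class{ContactSeries}.
#' @return A \linkS4class{ContactSeries} (frame x "basic_total" x lipid type).
#' @export
basicResidueContactTotal <- function(series) {
  stopifnot(is(series, "ContactSeries"))
  d <- dim(series@counts)
  if (d[1] == 0) stop("empty contact series")
  tot <- apply(series@counts >= 1, c(1, 3), sum)
  arr <- array(as.integer(tot), dim = c(d[1], 1, d[3]),
               dimnames = list(NULL, "basic_total",
                               dimnames(series@counts)[[3]]))
  new("ContactSeries", counts = arr, times = series@times)
}
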