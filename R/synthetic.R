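# run expr with a local RNG seeded at `seed`, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a competition titration curve
#'
#' Generates fluorescence values from the hyperbolic single-site
#' competitive-inhibition model
#' F = deltaFmax * (1 - x/(ic50 + x)) + offset plus additive Gaussian noise
#' with standard deviation \code{noiseSd * deltaFmax}. Output is
#' deterministic per seed. The default truth (IC50 620 micromolar, unit
#' amplitude, 2 percent noise) emulates the plasma-membrane-mimetic
#' competition titration regime.
#'
#' @param ic50 true half-displacement concentration, micromolar.
#' @param deltaFmax true amplitude.
#' @param offset true baseline.
#' @param grid titrant concentrations, micromolar; default is a zero point
#'   followed by 19 log-spaced points spanning 1 to 20000.
#' @param noiseSd noise standard deviation as a fraction of deltaFmax.
#' @param seed integer RNG seed.
#' @param compositionLabel label stored on the curve.
#' @return list with \code{curve} (\linkS4class{TitrationCurve}) and
#'   \code{truth} (list of the generating parameters).
#' @export
simulateTitration <- function(ic50 = 620, deltaFmax = 1, offset = 0,
                              grid = NULL, noiseSd = 0.02, seed = 1,
                              compositionLabel = "PM") {
  if (is.null(grid))
    grid <- c(0, 10^seq(0, log10(2e4), length.out = 19))
  if (!length(grid)) stop("invalid argument: empty titrant grid")
  if (any(diff(grid) <= 0)) stop("invalid argument: grid must be ascending")
  stopifnot(noiseSd >= 0, ic50 > 0)
  f <- deltaFmax * (1 - grid / (ic50 + grid)) + offset
  noisy <- .withSeed(seed,
                     f + stats::rnorm(length(grid), 0, noiseSd * deltaFmax))
  list(
    curve = TitrationCurve(grid, noisy, compositionLabel = compositionLabel),
    truth = list(ic50 = ic50, deltaFmax = deltaFmax, offset = offset,
                 noiseSd = noiseSd, seed = seed)
  )
}

#' Simulate a stopped-flow kinetic trace
#'
#' Generates an association trace
#' F = amplitude * (1 - exp(-k t)) + offset, or a single/double exponential
#' decay, on a half-open time grid (0 inclusive, duration exclusive, step
#' dt), with additive Gaussian noise of standard deviation
#' \code{noiseSd * totalAmplitude}. Points before the instrument dead time
#' are present in the trace (fitting excludes them); the defaults emulate a
#' 1.4 ms dead time. The default double-exponential truth (rates 1.0 and
#' 0.14 per second at 35/65 percent amplitude) mirrors the
#' plasma-membrane-mimetic dissociation regime.
#'
#' @param model \code{"association"}, \code{"single"} or \code{"double"}.
#' @param rates true rate constant(s), 1/s; length 2 (fast, slow) for
#'   \code{"double"}.
#' @param amplitudes true amplitude(s); same length as rates.
#' @param offset true baseline.
#' @param dt time step, seconds.
#' @param duration trace duration, seconds; defaults to 0.2 for association
#'   and 5 relaxation times of the slowest rate otherwise.
#' @param deadTime instrument dead time, seconds.
#' @param noiseSd noise standard deviation as a fraction of the total
#'   amplitude.
#' @param seed integer RNG seed.
#' @return list with \code{trace} (\linkS4class{KineticTrace}) and
#'   \code{truth}.
#' @export
simulateKineticTrace <- function(model = c("association", "single", "double"),
                                 rates = NULL, amplitudes = NULL, offset = 0,
                                 dt = NULL, duration = NULL,
                                 deadTime = 0.0014, noiseSd = 0.01,
                                 seed = 1) {
  model <- match.arg(model)
  if (is.null(rates))
    rates <- switch(model, association = 30, single = 1.0, double = c(1.0, 0.14))
  if (any(rates <= 0)) stop("invalid argument: rates must be positive")
  if (is.null(amplitudes))
    amplitudes <- switch(model, association = 1, single = 1,
                         double = c(0.35, 0.65))
  stopifnot(length(amplitudes) == length(rates))
  if (is.null(duration))
    duration <- if (model == "association") max(0.2, 5 / min(rates))
                else 5 / min(rates)
  if (duration <= deadTime)
    stop("invalid argument: duration must exceed the dead time")
  if (is.null(dt)) dt <- duration / 1000
  t <- seq(0, by = dt, length.out = floor(duration / dt))
  f <- if (model == "association")
    amplitudes[1] * (1 - exp(-rates[1] * t)) + offset
  else
    rowSums(vapply(seq_along(rates),
                   function(i) amplitudes[i] * exp(-rates[i] * t),
                   numeric(length(t)))) + offset
  total <- sum(amplitudes)
  noisy <- .withSeed(seed, f + stats::rnorm(length(t), 0, noiseSd * total))
  list(
    trace = KineticTrace(t, noisy, deadTime = deadTime),
    truth = list(model = model, rates = rates, amplitudes = amplitudes,
                 amplitudeFractions = 100 * amplitudes / total,
                 offset = offset, deadTime = deadTime, noiseSd = noiseSd,
                 seed = seed)
  )
}

# one synthetic lipid: phosphodiester P plus two headgroup oxygens and a
# tail carbon (the tail atom is outside every headgroup atom list)
.lipidAtoms <- function(resname, resno, segid, x, y, zP, zSign) {
  data.frame(
    atom = c("P", "O13", "O14", "C28"),
    element = c("P", "O", "O", "C"),
    resname = resname, resno = resno, segid = segid,
    x = x + c(0, 0.5, -0.5, 0),
    y = y + c(0, 0.5, -0.5, 0),
    z = zP + zSign * c(0, -0.3, -0.3, -8),
    mass = c(30.974, 15.999, 15.999, 12.011),
    stringsAsFactors = FALSE)
}

#' Build synthetic bilayer-plus-protein coordinate frames
#'
#' Constructs a planar lipid lattice (typed headgroup atoms at the declared
#' leaflet heights, protein-facing leaflet on top) and a pseudo-protein
#' carrying Lys NZ / Arg CZ / His ring anchor atoms plus a C-alpha backbone,
#' then emits one frame per row of the contact schedule. Anchor positions
#' are chosen per frame so that each basic residue contacts exactly the
#' scheduled number of distinct lipid molecules of its assigned lipid type
#' (0, 1 or 2), with all other lipids well outside the contact cutoffs.
#' Three C-alpha-only loop-tip triplets are included so loop-tip and
#' interloop-angle metrics have known values. Analytic ground truth for
#' every geometry metric is recorded.
#'
#' @param nLipids named integer vector, lipids per type in the
#'   protein-facing leaflet (the lower leaflet is PC with the same total).
#' @param spacing lattice spacing, angstrom.
#' @param leafletZ absolute z of the phosphate planes (upper at +leafletZ,
#'   lower at -leafletZ).
#' @param comHeight target protein center-of-mass height above the upper
#'   phosphate plane, angstrom.
#' @param basicResidues data.frame with columns resno, resname (LYS, ARG or
#'   HIS) and type (assigned lipid type); default: K398 on PIP2, R411 on PS,
#'   H449 on PS. Residue numbers must not collide with the loop-tip
#'   triplets (388-390, 406-408, 450-452).
#' @param schedule integer array/matrix (frames x basic residues) of
#'   scheduled contact counts in 0..2; default: 20 frames drawn from
#'   {0, 1, 2} with the given seed.
#' @param nFrames number of frames when \code{schedule} is NULL.
#' @param frameDt time between frames, nanoseconds.
#' @param seed integer RNG seed (used only for the default schedule).
#' @return list with \code{trajectory} (\linkS4class{MembraneTrajectory})
#'   and \code{truth} (plane z, COM height, per-residue depths, loop tips,
#'   interloop angle, and the contact schedule with its lipid types).
#' @export
buildMembraneProteinFrames <- function(
    nLipids = c(PC = 49, PS = 12, PIP2 = 3),
    spacing = 8, leafletZ = 20, comHeight = 23,
    basicResidues = NULL, schedule = NULL, nFrames = 20, frameDt = 0.1,
    seed = 1) {
  if (sum(nLipids) < 1) stop("at least one lipid required")
  if (is.null(basicResidues))
    basicResidues <- data.frame(
      resno = c(398L, 411L, 449L),
      resname = c("LYS", "ARG", "HIS"),
      type = c("PIP2", "PS", "PS"),
      stringsAsFactors = FALSE)
  if (!all(basicResidues$type %in% names(nLipids)))
    stop("basic residue assigned to a lipid type with no lipids")
  nb <- nrow(basicResidues)
  if (is.null(schedule)) {
    schedule <- .withSeed(seed, matrix(
      sample(0:2, nFrames * nb, replace = TRUE), nrow = nFrames))
  }
  schedule <- as.matrix(schedule)
  if (ncol(schedule) != nb)
    stop("schedule must have one column per basic residue")
  if (any(schedule < 0 | schedule > 2))
    stop("scheduled contact counts must be 0, 1 or 2")
  nFrames <- nrow(schedule)

  # lipid lattice: upper (protein-facing) leaflet typed, lower leaflet PC.
  # For each basic residue, two laterally adjacent "station" slots of its
  # assigned type are reserved in a dedicated lattice row; other lipids of
  # the same type may sit anywhere else, since any non-station lattice slot
  # is at least one spacing (8 A > all cutoffs) away laterally.
  nUpper <- sum(nLipids)
  side <- max(ceiling(sqrt(nUpper)), 2, nb)
  gx <- (seq_len(side) - 1) * spacing
  grid <- expand.grid(x = gx, y = gx)[seq_len(nUpper), ]
  types <- rep("PC", nUpper)
  for (i in seq_len(nb)) {
    s1 <- (i - 1) * side + 1L
    s2 <- s1 + 1L
    if (s2 > nUpper)
      stop("lattice too small to host all basic residues; increase nLipids")
    types[c(s1, s2)] <- basicResidues$type[i]
    basicResidues$station1[i] <- s1
    basicResidues$station2[i] <- s2
  }
  # fill trailing non-station PC slots with the remaining per-type quota
  free <- rev(setdiff(seq_len(nUpper),
                      c(basicResidues$station1, basicResidues$station2)))
  for (tp in setdiff(names(nLipids), "PC")) {
    need <- nLipids[[tp]] - sum(types == tp)
    if (need < 0)
      stop("not enough lipids of type ", tp,
           " to host the assigned basic residues")
    if (need > 0) {
      types[free[seq_len(need)]] <- tp
      free <- free[-seq_len(need)]
    }
  }
  if (sum(types == "PC") != nLipids[["PC"]])
    stop("lipid type counts are inconsistent with the station reservations")
  resnameOf <- c(PC = "POPC", PS = "POPS", PIP2 = "SAPI")
  lipids <- vector("list", 2 * nUpper)
  for (i in seq_len(nUpper)) {
    lipids[[i]] <- .lipidAtoms(resnameOf[[types[i]]], i, "MEMB",
                               grid$x[i], grid$y[i], leafletZ, +1)
    lipids[[nUpper + i]] <- .lipidAtoms("POPC", nUpper + i, "MEMB",
                                        grid$x[i], grid$y[i], -leafletZ, -1)
  }
  lipidDf <- do.call(rbind, lipids)
  boxL <- side * spacing * 4  # generous box: no wrap-around contacts
  center <- c(mean(gx), mean(gx))

  cutoffs <- c(LYS = 5.0, ARG = 6.3, HIS = 6.1)

  # static loop-tip triplets at fixed offsets above the membrane; the inert
  # 3x3 C-alpha body plate's height is solved per frame so the protein COM
  # sits exactly comHeight above the upper phosphate plane
  tipZ <- leafletZ + comHeight + 6
  tipOffsets <- list(
    "beta2-beta3" = c(10, 0),
    "beta6-beta7" = c(0, 10),
    "beta3-beta4" = c(-10, 0))
  tipRes <- list("beta2-beta3" = 388:390, "beta6-beta7" = 450:452,
                 "beta3-beta4" = 406:408)
  tipDf <- do.call(rbind, lapply(names(tipOffsets), function(nm) {
    off <- tipOffsets[[nm]]
    data.frame(
      atom = "CA", element = "C", resname = "GLY", resno = tipRes[[nm]],
      segid = "PROA",
      x = center[1] + off[1] + c(-1, 0, 1),
      y = center[2] + off[2],
      z = tipZ,
      mass = 12.011, stringsAsFactors = FALSE)
  }))
  plate <- expand.grid(dx = c(-3, 0, 3), dy = c(-3, 0, 3))
  bodyDf <- data.frame(
    atom = "CA", element = "C", resname = "GLY",
    resno = 300L + seq_len(nrow(plate)), segid = "PROA",
    x = center[1] + plate$dx, y = center[2] + plate$dy,
    z = NA_real_,  # solved per frame
    mass = 12.011, stringsAsFactors = FALSE)

  .basicResidueAtoms <- function(resname, resno, anchor) {
    if (resname == "LYS")
      data.frame(atom = c("CA", "NZ"), element = c("C", "N"),
                 resname = "LYS", resno = resno, segid = "PROA",
                 x = anchor[1], y = anchor[2], z = anchor[3] + c(1.5, 0),
                 mass = c(12.011, 14.007), stringsAsFactors = FALSE)
    else if (resname == "ARG")
      data.frame(atom = c("CA", "CZ"), element = c("C", "C"),
                 resname = "ARG", resno = resno, segid = "PROA",
                 x = anchor[1], y = anchor[2], z = anchor[3] + c(1.5, 0),
                 mass = 12.011, stringsAsFactors = FALSE)
    else {
      # imidazole ring: regular pentagon of radius 1.14 A centered on anchor
      ang <- 2 * pi * (0:4) / 5
      rbind(
        data.frame(atom = "CA", element = "C", resname = "HSD",
                   resno = resno, segid = "PROA",
                   x = anchor[1], y = anchor[2], z = anchor[3] + 1.5,
                   mass = 12.011, stringsAsFactors = FALSE),
        data.frame(atom = .HIS_RING_ATOMS,
                   element = c("C", "N", "C", "C", "N"),
                   resname = "HSD", resno = resno, segid = "PROA",
                   x = anchor[1] + 1.14 * cos(ang),
                   y = anchor[2] + 1.14 * sin(ang),
                   z = anchor[3],
                   mass = c(12.011, 14.007, 12.011, 12.011, 14.007),
                   stringsAsFactors = FALSE))
    }
  }

  # ring-COM anchors coincide with `anchor` by symmetry of the pentagon
  frameList <- vector("list", nFrames)
  depthTruth <- matrix(NA_real_, nFrames, nb)
  angleTruth <- numeric(nFrames)
  comTruth <- matrix(NA_real_, nFrames, 3)
  for (fi in seq_len(nFrames)) {
    protParts <- list(tipDf)
    for (bi in seq_len(nb)) {
      k <- schedule[fi, bi]
      rn <- basicResidues$resname[bi]
      cut <- cutoffs[[rn]]
      s1 <- basicResidues$station1[bi]
      s2 <- basicResidues$station2[bi]
      if (k == 0) {
        anchor <- c(grid$x[s1], grid$y[s1], leafletZ + 15)
      } else if (k == 1) {
        anchor <- c(grid$x[s1], grid$y[s1], leafletZ + 0.6 * cut)
      } else {
        anchor <- c((grid$x[s1] + grid$x[s2]) / 2, grid$y[s1],
                    leafletZ + 1.5)
      }
      protParts[[length(protParts) + 1L]] <-
        .basicResidueAtoms(rn, basicResidues$resno[bi], anchor)
      depthTruth[fi, bi] <- anchor[3] + 1.5 - leafletZ
    }
    restDf <- do.call(rbind, protParts)
    # solve the body-plate height so the protein COM z is exactly on target;
    # anchors stay untouched, preserving the scheduled contact geometry
    target <- leafletZ + comHeight
    mBody <- sum(bodyDf$mass)
    mRest <- sum(restDf$mass)
    body <- bodyDf
    body$z <- (target * (mBody + mRest) - sum(restDf$mass * restDf$z)) / mBody
    protDf <- rbind(body, restDf)
    mTot <- sum(protDf$mass)
    com <- c(sum(protDf$mass * protDf$x), sum(protDf$mass * protDf$y),
             sum(protDf$mass * protDf$z)) / mTot
    comTruth[fi, ] <- com
    # analytic interloop angle beta2-beta3 vs beta6-beta7 at the COM
    tipA <- c(center[1] + tipOffsets[["beta2-beta3"]][1],
              center[2] + tipOffsets[["beta2-beta3"]][2], tipZ)
    tipB <- c(center[1] + tipOffsets[["beta6-beta7"]][1],
              center[2] + tipOffsets[["beta6-beta7"]][2], tipZ)
    va <- tipA - com; vb <- tipB - com
    angleTruth[fi] <- acos(sum(va * vb) /
                             sqrt(sum(va^2) * sum(vb^2))) * 180 / pi
    allDf <- rbind(lipidDf, protDf)
    dup <- duplicated(round(allDf[, c("x", "y", "z")], 3))
    if (any(dup)) stop("generation error: overlapping atom placements")
    frameList[[fi]] <- MembraneFrame(allDf, box = c(boxL, boxL, 200),
                                     time = (fi - 1) * frameDt)
  }

  tips <- lapply(tipOffsets, function(off)
    c(center[1] + off[1], center[2] + off[2], tipZ))

  residLabels <- paste0(.AA1[basicResidues$resname], basicResidues$resno)
  colnames(depthTruth) <- residLabels
  colnames(schedule) <- residLabels
  list(
    trajectory = MembraneTrajectory(frameList),
    truth = list(
      planeZ = leafletZ, comHeight = comHeight,
      com = comTruth,
      anchorDepth = depthTruth - 1.5,  # anchor z minus plane
      caDepth = depthTruth,
      schedule = schedule,
      residueTypes = stats::setNames(basicResidues$type, residLabels),
      loopTips = tips,
      interloopAngle = angleTruth,
      seed = seed)
  )
}

#' Sample a Gaussian-mixture pose cloud
#'
#' Draws n ligand reference points from a mixture of isotropic Gaussians
#' around named site centers, recording the true component of every pose.
#' The default size (510 poses) emulates a docking campaign of 510 runs.
#'
#' @param centers numeric matrix, k x 3, component centers (angstrom).
#' @param weights numeric, component weights summing to 1.
#' @param sd isotropic standard deviation, angstrom.
#' @param n number of poses.
#' @param seed integer RNG seed.
#' @return list with \code{poses} (\linkS4class{PoseSet}) and \code{truth}
#'   (component labels and parameters).
#' @export
samplePoseCloud <- function(centers, weights, sd = 1.5, n = 510, seed = 1) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3, length(weights) == nrow(centers))
  if (abs(sum(weights) - 1) > 1e-9)
    stop("invalid argument: weights must sum to 1")
  if (any(weights < 0)) stop("invalid argument: negative weight")
  if (sd <= 0) stop("invalid argument: sd must be positive")
  out <- .withSeed(seed, {
    comp <- sample.int(nrow(centers), n, replace = TRUE, prob = weights)
    pos <- centers[comp, , drop = FALSE] +
      matrix(stats::rnorm(3 * n, 0, sd), ncol = 3)
    list(comp = comp, pos = pos)
  })
  list(
    poses = PoseSet(out$pos, runLabels = sprintf("run%03d", seq_len(n))),
    truth = list(component = out$comp, centers = centers, weights = weights,
                 sd = sd, seed = seed)
  )
}
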