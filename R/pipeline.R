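#' Default pipeline configuration
#'
#' All assay constants are surfaced here with their standard values:
#' inhibitor dissociation constant 1.8 micromolar, bulk water 55.5 M,
#' temperature 298.15 K, equilibrium total lipid 125 micromolar (62.5
#' accessible), stopped-flow accessible lipid 75 micromolar before
#' equal-volume mixing (37.5 after), 1.4 ms dead time.
#'
#' @param seed integer seed propagated to every stochastic stage.
#' @param stages character vector of stages to run, any of
#'   \code{"titration"}, \code{"kinetics"}, \code{"masses"},
#'   \code{"membrane"}, \code{"poses"}.
#' @return Nested list of configuration values.
#' @export
defaultRunConfig <- function(seed = 1,
                             stages = c("titration", "kinetics", "masses")) {
  list(
    seed = seed,
    stages = stages,
    constants = list(
      ki = 1.8, waterMolarity = 55.5, temperature = 298.15,
      totalLipidEquilibrium = 125,
      accessibleLipidStoppedFlow = 37.5,
      deadTime = 0.0014
    ),
    titration = list(curvePath = NULL, controlPath = NULL, ic50Truth = 620,
                     noiseSd = 0.02),
    kinetics = list(assocPath = NULL, dissocPath = NULL, kObsTruth = 30,
                    dissocRates = c(1.0, 0.14),
                    dissocAmplitudes = c(0.35, 0.65),
                    noiseSd = 0.01, kOffChoice = "fast"),
    masses = list(observedShifts = c(258, 80)),
    membrane = list(framesPath = NULL, nFrames = 10),
    poses = list(posesPath = NULL, n = 510)
  )
}

# fill missing entries of `config` from the defaults, recursively
.mergeConfig <- function(config, defaults) {
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]) && is.list(config[[nm]]))
      config[[nm]] <- .mergeConfig(config[[nm]], defaults[[nm]])
  }
  config
}

#' Read a pipeline configuration from a YAML file
#'
#' Missing keys are filled from \code{\link{defaultRunConfig}}.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .mergeConfig(cfg, defaultRunConfig())
}

.stageTitration <- function(config) {
  cc <- config$constants
  tcfg <- config$titration
  if (!is.null(tcfg$curvePath)) {
    if (!file.exists(tcfg$curvePath))
      stop("configuration error: titration curve file not found: ",
           tcfg$curvePath)
    curve <- readTitrationCsv(tcfg$curvePath)
  } else {
    curve <- simulateTitration(ic50 = tcfg$ic50Truth, noiseSd = tcfg$noiseSd,
                               seed = config$seed)$curve
  }
  if (!is.null(tcfg$controlPath)) {
    curve <- applyTitrationControls(curve, readTitrationCsv(tcfg$controlPath))
  }
  fit <- fitCompetitionTitration(curve)
  inputs <- PartitioningInputs(
    ki = cc$ki, waterMolarity = cc$waterMolarity,
    accessibleLipid = accessibleLipidConcentration(curve@totalLipidConc),
    temperature = cc$temperature)
  part <- ic50ToPartitionCoefficient(ic50(fit), inputs)
  list(
    composition = curve@compositionLabel,
    ic50 = ic50(fit),
    ic50StdError = unname(stdErrors(fit)["ic50"]),
    deltaFmax = deltaFmax(fit),
    offset = offsetC(fit),
    kx = partitionCoefficient(part),
    deltaG = freeEnergy(part),
    kxFormatted = formatKx(partitionCoefficient(part)),
    deltaGFormatted = formatDeltaG(freeEnergy(part))
  )
}

.stageKinetics <- function(config) {
  cc <- config$constants
  kcfg <- config$kinetics
  if (!is.null(kcfg$assocPath)) {
    assocTrace <- readTraceCsv(kcfg$assocPath)
    if (is.list(assocTrace)) assocTrace <- averageReplicateTraces(assocTrace)
  } else {
    reps <- lapply(seq_len(8), function(i)
      simulateKineticTrace("association", rates = kcfg$kObsTruth,
                           noiseSd = kcfg$noiseSd,
                           deadTime = cc$deadTime,
                           seed = config$seed * 100 + i)$trace)
    assocTrace <- averageReplicateTraces(reps)
  }
  assocFit <- fitAssociation(assocTrace)
  if (!is.null(kcfg$dissocPath)) {
    dissocTrace <- readTraceCsv(kcfg$dissocPath)
    if (is.list(dissocTrace))
      dissocTrace <- averageReplicateTraces(dissocTrace)
  } else {
    reps <- lapply(seq_len(8), function(i)
      simulateKineticTrace("double", rates = kcfg$dissocRates,
                           amplitudes = kcfg$dissocAmplitudes,
                           noiseSd = kcfg$noiseSd, deadTime = cc$deadTime,
                           seed = config$seed * 100 + 50 + i)$trace)
    dissocTrace <- averageReplicateTraces(reps)
  }
  dissocFit <- fitDissociation(dissocTrace, model = "auto")
  kOff <- switch(kcfg$kOffChoice,
    fast = offRates(dissocFit)[1],
    slow = offRates(dissocFit)[length(offRates(dissocFit))],
    weighted = sum(offRates(dissocFit) * amplitudes(dissocFit)) /
      sum(amplitudes(dissocFit)),
    stop("configuration error: kOffChoice must be fast, slow or weighted"))
  inputs <- PartitioningInputs(
    ki = cc$ki, waterMolarity = cc$waterMolarity,
    accessibleLipid = cc$accessibleLipidStoppedFlow,
    temperature = cc$temperature)
  rate <- associationRateConstant(kObs(assocFit), kOff, inputs)
  list(
    kObs = kObs(assocFit),
    dissocModel = dissocFit@model,
    kOffRates = offRates(dissocFit),
    amplitudeFractions = amplitudeFractions(dissocFit),
    kOffUsed = kOff,
    kOffChoice = kcfg$kOffChoice,
    konX = konX(rate),
    konXper1e6 = konX(rate) / 1e6
  )
}

.stageMasses <- function(config) {
  mods <- standardModifications()
  shifts <- config$masses$observedShifts
  matches <- lapply(shifts, function(s) {
    m <- matchIntactMassShift(s, mods)
    if (nrow(m)) m$observedShift <- s
    m
  })
  list(
    modificationMasses = lapply(mods, modificationMass),
    shiftMatches = do.call(rbind, matches)
  )
}

.stageMembrane <- function(config) {
  mcfg <- config$membrane
  if (!is.null(mcfg$framesPath)) {
    if (!file.exists(mcfg$framesPath))
      stop("configuration error: frames file not found: ", mcfg$framesPath)
    traj <- readMembraneFrames(mcfg$framesPath)
  } else {
    traj <- buildMembraneProteinFrames(nFrames = mcfg$nFrames,
                                       seed = config$seed)$trajectory
  }
  f1 <- frames(traj)[[1]]
  planeZ <- phosphatePlaneZ(f1, "protein_facing")
  series <- lipidContactSeries(traj)
  stats <- contactTimeStatistics(series, list(lastFraction = 0.5))
  list(
    planeZ = planeZ,
    comHeight = vapply(frames(traj), proteinComHeight, numeric(1)),
    contactStatistics = stats,
    basicTotals = contactTimeStatistics(basicResidueContactTotal(series),
                                        list(lastFraction = 0.5))
  )
}

.stagePoses <- function(config) {
  pcfg <- config$poses
  sim <- NULL
  if (!is.null(pcfg$posesPath)) {
    poses <- readPoseCsv(pcfg$posesPath)
  } else {
    centers <- rbind(lys_cluster = c(0, 0, 0), loops = c(30, 0, 0),
                     far = c(0, 40, 0))
    sim <- samplePoseCloud(centers, weights = c(0.6, 0.3, 0.1), sd = 1.5,
                           n = pcfg$n, seed = config$seed)
    poses <- sim$poses
  }
  labels <- clusterPoses(poses, linkageCutoff = 5)
  list(
    nPoses = length(labels),
    nClusters = length(unique(labels)),
    clusterSizes = as.integer(table(labels)),
    largestClusterFraction = max(tabulate(labels)) / length(labels)
  )
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order and assembles a run report with
#' provenance (configuration hash, seed, package version). Identical
#' configuration and seed produce an identical numeric payload. A stage
#' failure is recorded in the report's \code{errors} and does not abort the
#' remaining stages; missing input files are raised as configuration errors
#' before computation.
#'
#' @param config configuration list, see \code{\link{defaultRunConfig}}.
#' @return Run report list with \code{results}, \code{provenance},
#'   \code{warnings} and \code{errors}.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  config <- .mergeConfig(config, defaultRunConfig())
  known <- c("titration", "kinetics", "masses", "membrane", "poses")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    stop("configuration error: unknown stage(s): ",
         paste(bad, collapse = ", "))
  stageFns <- list(titration = .stageTitration, kinetics = .stageKinetics,
                   masses = .stageMasses, membrane = .stageMembrane,
                   poses = .stagePoses)
  results <- list()
  warns <- character(0)
  errors <- list()
  for (st in config$stages) {
    res <- withCallingHandlers(
      tryCatch(stageFns[[st]](config), error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, paste0(st, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "error"))
      errors[[st]] <- conditionMessage(res)
    else results[[st]] <- res
  }
  cfgFile <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfgFile, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  hash <- unname(tools::md5sum(cfgFile))
  unlink(cfgFile)
  list(
    results = results,
    provenance = list(
      configHash = hash,
      seed = config$seed,
      packageVersion = as.character(utils::packageVersion("C2MemBind")),
      constants = config$constants
    ),
    warnings = warns,
    errors = errors
  )
}

#' Render a run report to files
#'
#' JSON output is a lossless serialization of the report; TSV output writes
#' one file per tabular result; markdown output is a human-readable summary
#' using the standard table formatting (partition coefficients in units of
#' 1e6 at two significant figures, free energies at one decimal).
#'
#' @param report a report from \code{\link{runPipeline}}.
#' @param format \code{"json"}, \code{"tsv"} or \code{"markdown"}.
#' @param dir output directory (created if needed).
#' @return Character vector of files written.
#' @export
renderReport <- function(report, format = c("json", "tsv", "markdown"),
                         dir = ".") {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (format == "json") {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE, dataframe = "columns")
    written <- path
  } else if (format == "tsv") {
    for (st in names(report$results)) {
      res <- report$results[[st]]
      tab <- if (is.data.frame(res)) res else {
        flat <- res[vapply(res, function(x)
          is.atomic(x) && length(x) == 1, logical(1))]
        if (!length(flat)) next
        data.frame(metric = names(flat),
                   value = vapply(flat, as.character, character(1)))
      }
      path <- file.path(dir, paste0(st, ".tsv"))
      utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      written <- c(written, path)
      if (is.list(res) && !is.data.frame(res)) {
        for (nm in names(res)) {
          if (is.data.frame(res[[nm]])) {
            p2 <- file.path(dir, paste0(st, "_", nm, ".tsv"))
            utils::write.table(res[[nm]], p2, sep = "\t",
                               row.names = FALSE, quote = FALSE)
            written <- c(written, p2)
          }
        }
      }
    }
    if (!length(written)) {
      path <- file.path(dir, "results.tsv")
      utils::write.table(data.frame(metric = character(0),
                                    value = character(0)),
                         path, sep = "\t", row.names = FALSE, quote = FALSE)
      written <- path
    }
  } else {
    path <- file.path(dir, "report.md")
    lines <- c("# Membrane-binding analysis report", "")
    tit <- report$results$titration
    if (!is.null(tit)) {
      lines <- c(lines, "## Equilibrium partitioning", "",
                 "| Composition | IC50 (uM) | Kx x 1e-6 | dG (kcal/mol) |",
                 "|---|---|---|---|",
                 sprintf("| %s | %.3g | %s | %s |", tit$composition,
                         tit$ic50, tit$kxFormatted, tit$deltaGFormatted), "")
    }
    kin <- report$results$kinetics
    if (!is.null(kin)) {
      lines <- c(lines, "## Stopped-flow kinetics", "",
                 sprintf("- k_obs = %.3g /s", kin$kObs),
                 sprintf("- dissociation model: %s", kin$dissocModel),
                 sprintf("- k_off = %s /s",
                         paste(sprintf("%.3g (%.0f%% amp)", kin$kOffRates,
                                       kin$amplitudeFractions),
                               collapse = ", ")),
                 sprintf("- kon,x = %.3g /s (%s x 1e6, using %s k_off)",
                         kin$konX, format(signif(kin$konXper1e6, 2)),
                         kin$kOffChoice), "")
    }
    lines <- c(lines, sprintf("Seed: %d; config %s",
                              report$provenance$seed,
                              report$provenance$configHash))
    writeLines(lines, path)
    written <- path
  }
  written
}
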