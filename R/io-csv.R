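# parse "# key: value" comment headers at the top of a CSV file
.readHashHeader <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv
}

#' Read a titration curve from CSV
#'
#' Expects columns \code{titrant_conc_uM, fluorescence} and optional
#' \code{# key: value} header lines for \code{titrant_kind},
#' \code{protein_conc_uM}, \code{total_lipid_uM} and
#' \code{composition_label}.
#'
#' @param path CSV file path.
#' @return A \linkS4class{TitrationCurve}.
#' @export
readTitrationCsv <- function(path) {
  kv <- .readHashHeader(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("titrant_conc_uM", "fluorescence") %in% names(df)))
    stop("data format error: expected columns titrant_conc_uM, fluorescence")
  TitrationCurve(
    df$titrant_conc_uM, df$fluorescence,
    titrantKind = if (!is.null(kv$titrant_kind)) kv$titrant_kind else "IP6",
    proteinConc = if (!is.null(kv$protein_conc_uM))
      as.numeric(kv$protein_conc_uM) else 1,
    totalLipidConc = if (!is.null(kv$total_lipid_uM))
      as.numeric(kv$total_lipid_uM) else 125,
    compositionLabel = if (!is.null(kv$composition_label))
      kv$composition_label else "unknown")
}

#' Write a titration curve to CSV
#'
#' @param curve a \linkS4class{TitrationCurve}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeTitrationCsv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# titrant_kind: %s", curve@titrantKind),
    sprintf("# protein_conc_uM: %g", curve@proteinConc),
    sprintf("# total_lipid_uM: %g", curve@totalLipidConc),
    sprintf("# composition_label: %s", curve@compositionLabel),
    "titrant_conc_uM,fluorescence"), con)
  writeLines(sprintf("%.10g,%.10g", curve@titrantConc, curve@fluorescence),
             con)
  invisible(path)
}

#' Read a kinetic trace from CSV
#'
#' Expects columns \code{time_s, signal} and optional header keys
#' \code{dead_time_s} and \code{replicate_id}. A long-format file with a
#' \code{replicate} column yields a list of traces.
#'
#' @param path CSV file path.
#' @return A \linkS4class{KineticTrace}, or a list of them for long-format
#'   input.
#' @export
readTraceCsv <- function(path) {
  kv <- .readHashHeader(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "signal") %in% names(df)))
    stop("data format error: expected columns time_s, signal")
  dead <- if (!is.null(kv$dead_time_s)) as.numeric(kv$dead_time_s) else 0.0014
  if ("replicate" %in% names(df)) {
    lapply(split(df, df$replicate), function(d)
      KineticTrace(d$time_s, d$signal, deadTime = dead))
  } else {
    KineticTrace(df$time_s, df$signal, deadTime = dead)
  }
}

#' Write a kinetic trace to CSV
#'
#' @param trace a \linkS4class{KineticTrace}.
#' @param path output path.
#' @param replicateId optional replicate identifier written to the header.
#' @return Invisibly, the path.
#' @export
writeTraceCsv <- function(trace, path, replicateId = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dead_time_s: %g", trace@deadTime), con)
  if (!is.null(replicateId))
    writeLines(sprintf("# replicate_id: %s", replicateId), con)
  writeLines("time_s,signal", con)
  writeLines(sprintf("%.10g,%.10g", trace@time, trace@signal), con)
  invisible(path)
}

#' Read docked-pose positions from CSV
#'
#' Expects columns \code{run_id, x, y, z}.
#'
#' @param path CSV file path.
#' @return A \linkS4class{PoseSet}.
#' @export
readPoseCsv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("data format error: expected columns run_id, x, y, z")
  PoseSet(as.matrix(df[, c("x", "y", "z")]),
          runLabels = if ("run_id" %in% names(df))
            as.character(df$run_id) else character(0))
}

#' Write docked-pose positions to CSV
#'
#' @param poses a \linkS4class{PoseSet}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writePoseCsv <- function(poses, path) {
  labels <- if (length(poses@runLabels)) poses@runLabels
            else sprintf("run%03d", seq_len(nrow(poses@positions)))
  df <- data.frame(run_id = labels, poses@positions)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
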