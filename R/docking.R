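#' Single-linkage clustering of docked poses
#'
#' Agglomerative single-linkage clustering on Euclidean distance between pose
#' reference points; clusters are the connected components of the graph
#' linking poses closer than the cutoff. Labels are integers sorted by
#' descending cluster size, ties broken by the first-seen pose index, so the
#' labelling is deterministic given the input order.
#'
#' @param poses a \linkS4class{PoseSet}.
#' @param linkageCutoff merge distance cutoff in angstrom (default 5).
#' @return Integer vector of cluster labels, one per pose; label 1 is the
#'   largest cluster.
#' @examples
#' ps <- PoseSet(rbind(matrix(rnorm(30, sd = 0.5), 10),
#'                     matrix(rnorm(30, sd = 0.5) + 50, 10)))
#' table(clusterPoses(ps, 5))
#' @export
clusterPoses <- function(poses, linkageCutoff = 5) {
  stopifnot(is(poses, "PoseSet"), linkageCutoff > 0)
  n <- nrow(poses@positions)
  if (n == 1) return(1L)
  hc <- stats::hclust(stats::dist(poses@positions), method = "single")
  raw <- stats::cutree(hc, h = linkageCutoff)
  # relabel by descending size, ties by first occurrence
  firstSeen <- tapply(seq_len(n), raw, min)
  sizes <- tabulate(raw)
  ord <- order(-sizes, firstSeen)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  unname(relabel[raw])
}

# anchor point of a residue for site-center purposes: NZ (Lys), CZ (Arg),
# imidazole ring COM (His), C-alpha otherwise
.residueAnchorPoint <- function(frame, resno) {
  a <- frame@atoms[.isProtein(frame), , drop = FALSE]
  res <- a[a$resno == resno, , drop = FALSE]
  if (!nrow(res))
    stop("missing selection: residue ", resno, " not found in protein frame")
  rn <- res$resname[1]
  if (rn == "LYS" && any(res$atom == "NZ"))
    hit <- res[res$atom == "NZ", , drop = FALSE]
  else if (rn == "ARG" && any(res$atom == "CZ"))
    hit <- res[res$atom == "CZ", , drop = FALSE]
  else if (rn %in% .HIS_RESNAMES && any(res$atom %in% .HIS_RING_ATOMS)) {
    ring <- res[res$atom %in% .HIS_RING_ATOMS, , drop = FALSE]
    w <- ring$mass / sum(ring$mass)
    return(c(sum(w * ring$x), sum(w * ring$y), sum(w * ring$z)))
  } else if (any(res$atom == "CA"))
    hit <- res[res$atom == "CA", , drop = FALSE]
  else hit <- res[1, , drop = FALSE]
  c(hit$x[1], hit$y[1], hit$z[1])
}

#' Site center from a site definition
#'
#' Center of mass (equal weights) of the anchor points of the site's anchor
#' residues.
#'
#' @param site a \linkS4class{SiteDefinition}.
#' @param proteinFrame a \linkS4class{MembraneFrame} holding the protein.
#' @return numeric(3).
#' @export
siteCenter <- function(site, proteinFrame) {
  stopifnot(is(site, "SiteDefinition"))
  pts <- vapply(site@anchorResidues, function(rn)
    .residueAnchorPoint(proteinFrame, rn), numeric(3))
  rowMeans(pts)
}

#' Tabulate binding-site occupancy of clustered poses
#'
#' Each cluster is assigned to the named site whose center is nearest its
#' centroid, provided that distance is within \code{assignRadius}; otherwise
#' the cluster is "other". Fractions are over all poses and sum to 1.
#'
#' @param labels integer cluster labels from \code{\link{clusterPoses}}.
#' @param poses the \linkS4class{PoseSet} that was clustered.
#' @param sites list of \linkS4class{SiteDefinition}.
#' @param proteinFrame a \linkS4class{MembraneFrame} resolving the sites.
#' @param assignRadius maximum centroid-to-site-center distance in angstrom
#'   (default 8).
#' @return data.frame with columns site, nPoses, fraction; one row per named
#'   site plus "other".
#' @export
tabulateSiteOccupancy <- function(labels, poses, sites, proteinFrame,
                                  assignRadius = 8) {
  stopifnot(is(poses, "PoseSet"),
            length(labels) == nrow(poses@positions))
  centers <- vapply(sites, siteCenter, numeric(3),
                    proteinFrame = proteinFrame)
  siteNames <- vapply(sites, function(s) s@name, character(1))
  colnames(centers) <- siteNames
  n <- length(labels)
  assigned <- stats::setNames(integer(length(siteNames) + 1),
                              c(siteNames, "other"))
  for (cl in unique(labels)) {
    idx <- labels == cl
    centroid <- colMeans(poses@positions[idx, , drop = FALSE])
    d <- sqrt(colSums((centers - centroid)^2))
    target <- if (min(d) <= assignRadius) siteNames[which.min(d)] else "other"
    assigned[target] <- assigned[target] + sum(idx)
  }
  data.frame(site = names(assigned),
             nPoses = as.integer(assigned),
             fraction = as.numeric(assigned) / n,
             row.names = NULL)
}
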