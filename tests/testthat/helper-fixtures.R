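# shared fixtures and independent oracles for the test suite

# random rotation matrix (det +1) plus translation
randomRigid <- function(seed) {
  set.seed(seed)
  qr <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 20))
}

applyRigidToFrame <- function(frame, rigid) {
  a <- atoms(frame)
  xyz <- t(rigid$R %*% t(as.matrix(a[, c("x", "y", "z")])) + rigid$t)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  MembraneFrame(a, box = NULL, time = frame@time)
}

applyRigidToPoints <- function(pts, rigid) {
  t(rigid$R %*% t(pts) + rigid$t)
}

# random membrane-protein frame for contact testing: nLipid lipids with
# 3 headgroup atoms each, nBasic basic residues, uniformly placed in a cube
randomContactFrame <- function(seed, nLipid = 30, nBasic = 6, span = 40) {
  set.seed(seed)
  lipTypes <- sample(c("POPC", "POPS", "SAPI"), nLipid, replace = TRUE)
  lip <- do.call(rbind, lapply(seq_len(nLipid), function(i) {
    p <- runif(3, 0, span)
    data.frame(atom = c("P", "O13", "O14"), element = c("P", "O", "O"),
               resname = lipTypes[i], resno = i, segid = "MEMB",
               x = p[1] + c(0, runif(2, -1, 1)),
               y = p[2] + c(0, runif(2, -1, 1)),
               z = p[3] + c(0, runif(2, -1, 1)),
               mass = c(30.974, 15.999, 15.999))
  }))
  basics <- do.call(rbind, lapply(seq_len(nBasic), function(i) {
    rn <- sample(c("LYS", "ARG", "HSD"), 1)
    p <- runif(3, 0, span)
    if (rn == "LYS")
      data.frame(atom = c("CA", "NZ"), element = c("C", "N"),
                 resname = rn, resno = 100L + i, segid = "PROA",
                 x = p[1], y = p[2], z = p[3] + c(1.5, 0),
                 mass = c(12.011, 14.007))
    else if (rn == "ARG")
      data.frame(atom = c("CA", "CZ"), element = c("C", "C"),
                 resname = rn, resno = 100L + i, segid = "PROA",
                 x = p[1], y = p[2], z = p[3] + c(1.5, 0),
                 mass = c(12.011, 12.011))
    else {
      ang <- 2 * pi * (0:4) / 5
      data.frame(atom = c("CA", "CG", "ND1", "CD2", "CE1", "NE2"),
                 element = c("C", "C", "N", "C", "C", "N"),
                 resname = rn, resno = 100L + i, segid = "PROA",
                 x = p[1] + c(0, 1.14 * cos(ang)),
                 y = p[2] + c(0, 1.14 * sin(ang)),
                 z = p[3] + c(1.5, rep(0, 5)),
                 mass = c(12.011, 12.011, 14.007, 12.011, 12.011, 14.007))
    }
  }))
  MembraneFrame(rbind(lip, basics))
}

# O(N^2) all-pairs contact oracle: plain loops, no neighbor optimization
contactOracle <- function(frame, criteria = contactCriteria(),
                          headgroups = headgroupSpec()) {
  a <- atoms(frame)
  hisNames <- c("HIS", "HSD", "HSE", "HSP")
  protein <- a[a$resname %in% c("LYS", "ARG", hisNames), , drop = FALSE]
  lipid <- a[a$resname %in% names(headgroups$resnameMap) &
               a$element != "H", , drop = FALSE]
  resnos <- unique(protein$resno)
  types <- sort(unique(unname(headgroups$resnameMap[lipid$resname])))
  aa1 <- c(LYS = "K", ARG = "R", HIS = "H", HSD = "H", HSE = "H", HSP = "H")
  out <- matrix(0L, length(resnos), length(types))
  labels <- character(length(resnos))
  for (ri in seq_along(resnos)) {
    res <- protein[protein$resno == resnos[ri], , drop = FALSE]
    rn <- res$resname[1]
    labels[ri] <- paste0(aa1[[rn]], resnos[ri])
    if (rn == "LYS") {
      anchor <- unlist(res[res$atom == "NZ", c("x", "y", "z")])
      cutoff <- 5.0
    } else if (rn == "ARG") {
      anchor <- unlist(res[res$atom == "CZ", c("x", "y", "z")])
      cutoff <- 6.3
    } else {
      ring <- res[res$atom %in% c("CG", "ND1", "CD2", "CE1", "NE2"), ]
      anchor <- c(sum(ring$mass * ring$x), sum(ring$mass * ring$y),
                  sum(ring$mass * ring$z)) / sum(ring$mass)
      cutoff <- 6.1
    }
    for (mol in unique(lipid$resno)) {
      latoms <- lipid[lipid$resno == mol, , drop = FALSE]
      tp <- headgroups$resnameMap[[latoms$resname[1]]]
      hg <- latoms[latoms$atom %in% headgroups$atoms[[tp]], , drop = FALSE]
      touched <- FALSE
      for (k in seq_len(nrow(hg))) {
        d <- sqrt((hg$x[k] - anchor[1])^2 + (hg$y[k] - anchor[2])^2 +
                    (hg$z[k] - anchor[3])^2)
        if (d <= cutoff) { touched <- TRUE; break }
      }
      if (touched) {
        ci <- match(tp, types)
        out[ri, ci] <- out[ri, ci] + 1L
      }
    }
  }
  dimnames(out) <- list(labels, types)
  out
}

# simple frame holding only protein C-alpha atoms at given positions
caFrame <- function(resno, xyz, resname = "GLY") {
  xyz <- matrix(xyz, ncol = 3)
  MembraneFrame(data.frame(
    atom = "CA", element = "C", resname = resname, resno = resno,
    segid = "PROA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = 12.011))
}
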