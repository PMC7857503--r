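# monoisotopic and average atomic masses (Da)
.ATOMIC_MONO <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
                  O = 15.9949146221, P = 30.97376151, S = 31.97207069)
.ATOMIC_AVG <- c(H = 1.00794, C = 12.0107, N = 14.0067,
                 O = 15.9994, P = 30.973762, S = 32.065)

# monoisotopic residue masses (Da), standard amino-acid residues
.RESIDUE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

.MASS_WATER <- 18.0105646
.MASS_PROTON <- 1.00727646

#' Built-in modification definitions
#'
#' The modifications relevant to lysine-cluster adduct identification:
#' phosphogluconoyl (C6H11O9P, +258.01 Da, the ring-opened
#' 6-phosphogluconolactone adduct of lysine), phospho (HPO3, +79.97 Da),
#' oxidation (O) and carbamidomethyl (C2H3NO, the fixed cysteine
#' alkylation).
#'
#' @return Named list of \linkS4class{ModificationSpec}.
#' @export
standardModifications <- function() {
  list(
    phosphogluconoyl = ModificationSpec(
      "phosphogluconoyl", c(C = 6, H = 11, O = 9, P = 1), "K"),
    phospho = ModificationSpec("phospho", c(H = 1, P = 1, O = 3), "STY"),
    oxidation = ModificationSpec("oxidation", c(O = 1), "MW"),
    carbamidomethyl = ModificationSpec(
      "carbamidomethyl", c(C = 2, H = 3, N = 1, O = 1), "C", fixed = TRUE)
  )
}

#' Mass of a modification from its elemental composition
#'
#' Sums standard atomic masses over the element -> count composition.
#'
#' @param spec a \linkS4class{ModificationSpec}.
#' @return Named numeric with \code{monoisotopic} and \code{average} mass
#'   in daltons.
#' @examples
#' modificationMass(standardModifications()$phosphogluconoyl)  # ~258.01
#' @export
modificationMass <- function(spec) {
  stopifnot(is(spec, "ModificationSpec"))
  els <- names(spec@composition)
  unknown <- setdiff(els, names(.ATOMIC_MONO))
  if (length(unknown))
    stop("unknown element(s) in composition: ",
         paste(unknown, collapse = ", "))
  c(monoisotopic = sum(.ATOMIC_MONO[els] * spec@composition),
    average = sum(.ATOMIC_AVG[els] * spec@composition))
}

# per-position modification mass shifts (monoisotopic) for a peptide
.siteShifts <- function(peptide) {
  n <- nchar(peptide@sequence)
  shifts <- numeric(n)
  for (p in names(peptide@siteModifications)) {
    shifts[as.integer(p)] <- shifts[as.integer(p)] +
      modificationMass(peptide@siteModifications[[p]])[["monoisotopic"]]
  }
  shifts
}

# residue monoisotopic masses of a sequence, with errors for unknown letters
.residueMasses <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  if (!length(chars)) stop("sequence error: empty peptide sequence")
  m <- .RESIDUE_MONO[chars]
  if (any(is.na(m)))
    stop("sequence error: unknown residue letter(s): ",
         paste(unique(chars[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Monoisotopic mass of a (modified) peptide
#'
#' Sum of residue monoisotopic masses plus one water plus all site
#' modification masses.
#'
#' @param peptide a \linkS4class{ModifiedPeptide} or plain sequence string.
#' @return Monoisotopic mass in daltons.
#' @examples
#' peptideMonoisotopicMass("GG")  # 132.0535
#' @export
peptideMonoisotopicMass <- function(peptide) {
  if (is.character(peptide)) peptide <- ModifiedPeptide(peptide)
  res <- .residueMasses(peptide@sequence)
  sum(res) + .MASS_WATER + sum(.siteShifts(peptide))
}

#' Singly-charged b- and y-ion ladder of a peptide
#'
#' For a peptide of n residues, the n-1 b-ions (N-terminal fragments:
#' residue sum plus a proton) and n-1 y-ions (C-terminal fragments: residue
#' sum plus water plus a proton). Site modifications shift exactly the ions
#' whose fragment contains the modified position.
#'
#' @param peptide a \linkS4class{ModifiedPeptide} or plain sequence string.
#' @param charge fragment charge; only 1 is supported.
#' @return data.frame with columns ion (e.g. "b2", "y7"), series, index, mz.
#' @examples
#' pg <- ModificationSpec("phosphogluconoyl", c(C = 6, H = 11, O = 9, P = 1), "K")
#' ladder <- fragmentLadder(ModifiedPeptide("SNPYVkTYLLPD", list(k = pg)))
#' head(ladder)
#' @export
fragmentLadder <- function(peptide, charge = 1) {
  if (!identical(as.integer(charge), 1L))
    stop("only singly-charged fragments are supported")
  if (is.character(peptide)) peptide <- ModifiedPeptide(peptide)
  res <- .residueMasses(peptide@sequence)
  n <- length(res)
  if (n < 2) stop("sequence error: peptide must have at least 2 residues")
  shifted <- res + .siteShifts(peptide)
  bPrefix <- cumsum(shifted)[-n]
  ySuffix <- rev(cumsum(rev(shifted)))[-1]
  data.frame(
    ion = c(paste0("b", seq_len(n - 1)), paste0("y", seq_len(n - 1))),
    series = rep(c("b", "y"), each = n - 1),
    index = rep(seq_len(n - 1), 2),
    mz = c(bPrefix + .MASS_PROTON, rev(ySuffix) + .MASS_WATER + .MASS_PROTON),
    stringsAsFactors = FALSE)
}

#' Test a theoretical/observed mass pair against a ppm tolerance
#'
#' Symmetric parts-per-million criterion:
#' |observed - theoretical| / theoretical <= tolerance.
#'
#' @param theoretical theoretical mass (Da).
#' @param observed observed mass (Da).
#' @param ppm tolerance in ppm.
#' @return logical.
#' @export
withinPpm <- function(theoretical, observed, ppm) {
  abs(observed - theoretical) / theoretical * 1e6 <= ppm
}

#' Match an intact-protein mass shift against candidate modifications
#'
#' Finds single modifications, and sums of two (including the same
#' modification twice), whose mass falls within the intact tolerance of the
#' observed shift. Matches are evaluated against both monoisotopic and
#' average candidate masses (deconvoluted intact-protein spectra report
#' average masses; both round identically for the shifts of interest) and
#' ranked by absolute error.
#'
#' @param observedShift observed mass increase in daltons.
#' @param candidates named list of \linkS4class{ModificationSpec}.
#' @param policy a \linkS4class{TolerancePolicy}; \code{intactDa} is used.
#' @return data.frame with columns modifications (comma-joined names),
#'   monoisotopic, average, errorMono, errorAvg, error (min of the two
#'   absolute errors), sorted ascending by error. Zero rows when nothing
#'   matches.
#' @examples
#' matchIntactMassShift(258, standardModifications())
#' @export
matchIntactMassShift <- function(observedShift,
                                 candidates = standardModifications(),
                                 policy = TolerancePolicy()) {
  stopifnot(length(candidates) >= 1, is(policy, "TolerancePolicy"))
  masses <- vapply(candidates, modificationMass, numeric(2))
  nms <- names(candidates)
  combos <- data.frame(modifications = nms,
                       monoisotopic = masses["monoisotopic", ],
                       average = masses["average", ],
                       stringsAsFactors = FALSE)
  if (length(nms) >= 1) {
    idx <- which(upper.tri(diag(length(nms)), diag = TRUE), arr.ind = TRUE)
    pairs <- data.frame(
      modifications = paste(nms[idx[, 1]], nms[idx[, 2]], sep = " + "),
      monoisotopic = masses["monoisotopic", idx[, 1]] +
        masses["monoisotopic", idx[, 2]],
      average = masses["average", idx[, 1]] + masses["average", idx[, 2]],
      stringsAsFactors = FALSE)
    combos <- rbind(combos, pairs)
  }
  combos$errorMono <- combos$monoisotopic - observedShift
  combos$errorAvg <- combos$average - observedShift
  combos$error <- pmin(abs(combos$errorMono), abs(combos$errorAvg))
  hits <- combos[combos$error <= policy@intactDa, , drop = FALSE]
  hits <- hits[order(hits$error), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Enumerate mutually exclusive site assignments for an intact shift
#'
#' Given an observed intact-protein shift matching k copies of a
#' modification and a set of candidate sites, enumerates the site
#' combinations consistent with exactly k modified sites; with one copy,
#' candidate sites (e.g. the two lysines of a binding cluster) are mutually
#' exclusive alternatives.
#'
#' @param observedShift observed mass increase in daltons.
#' @param spec the \linkS4class{ModificationSpec} considered.
#' @param sites character vector of site labels, e.g. \code{c("K398",
#'   "K412")}.
#' @param policy a \linkS4class{TolerancePolicy}.
#' @return list with \code{nCopies} (best-matching copy number, 0 when no
#'   match) and \code{assignments} (list of site-label character vectors,
#'   each one a consistent assignment).
#' @export
enumerateSiteAssignments <- function(observedShift, spec, sites,
                                     policy = TolerancePolicy()) {
  stopifnot(is(spec, "ModificationSpec"))
  mono <- modificationMass(spec)[["monoisotopic"]]
  maxCopies <- length(sites)
  errs <- abs(observedShift - mono * seq_len(maxCopies))
  k <- which(errs <= policy@intactDa)
  if (!length(k)) return(list(nCopies = 0L, assignments = list()))
  k <- k[which.min(errs[k])]
  combos <- utils::combn(sites, k, simplify = FALSE)
  list(nCopies = as.integer(k), assignments = combos)
}
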