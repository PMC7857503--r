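---
title: "Quantifying polybasic C2 domain membrane binding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polybasic C2 domain membrane binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(C2MemBind)
```

C2MemBind analyses the membrane binding of polybasic, Ca²⁺-independent C2
domains along four experimental axes — equilibrium competition titrations,
stopped-flow kinetics, coordinate-frame geometry, and mass spectrometry of
lysine adducts — plus a synthetic-data module that generates inputs with
recorded ground truth. This vignette explains the models, the parameters
that matter, the numerical choices, and what the validation does and does
not demonstrate.

## Equilibrium partitioning

A tryptophan-to-dansyl FRET signal reports protein–membrane proximity.
Titrating with a soluble polyanionic competitor (IP₆) displaces the protein
from the membrane; the intensity follows the single-site competitive
inhibition hyperbola

$$F = \Delta F_{max}\left(1 - \frac{[\mathrm{IP_6}]}{IC_{50} +
[\mathrm{IP_6}]}\right) + C.$$

`fitCompetitionTitration()` estimates $(\Delta F_{max}, IC_{50}, C)$ by
Levenberg–Marquardt least squares. Starting values are derived from the
data — $IC_{50}$ from the titrant concentration at half the total signal
drop (linear interpolation), the amplitude from the first-minus-last
signal, the offset from the last point — and the amplitude and $IC_{50}$
are bounded below by zero. The model assumes one competitive site and that
the initial FRET need not represent complete binding (the offset absorbs
residual signal).

The thermodynamic conversion treats binding as partitioning between the
aqueous phase and the membrane pseudo-phase:

$$K_x = \left(\frac{IC_{50}}{K_I} - 1\right)\frac{[\mathrm{H_2O}]}{[L]},
\qquad \Delta G^\circ = -RT\ln K_x.$$

Parameters, units and defaults:

| parameter | meaning | default | rationale |
|---|---|---|---|
| $K_I$ | protein–IP₆ dissociation constant (μM) | 1.8 | independently measured affinity of the inhibitor for the protein; configurable |
| $[\mathrm{H_2O}]$ | bulk water concentration (M) | 55.5 | pure-water molarity at 25 °C; the conventional mole-fraction reference. 55.3 M (the value at higher solute load) changes $\Delta G$ by < 0.01 kcal/mol, far inside the experimental uncertainty, so the choice is immaterial and we fix 55.5 |
| $[L]$ | accessible lipid (μM) | 62.5 | half of 125 μM total lipid: only outer-leaflet lipids of a sonicated vesicle are available. `accessibleLipidConcentration()` also applies mixing dilutions (equal-volume stopped-flow mixing halves concentrations) |
| $T$ | temperature (K) | 298.15 | assays at 25 °C; paired with $R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹ |

Control handling (`applyTitrationControls()`): the lipid-only control
measures titrant effects on the acceptor fluorophore, so its drift relative
to its own first point is subtracted (additive correction — the artifact
adds to the intensity rather than scaling it); an optional buffer-dilution
control is divided out as a fractional signal-loss profile, which is the
natural form for volume-driven signal loss. NaCl screening curves are
control-corrected and normalized only; no binding model is fitted to them.

## Stopped-flow kinetics

Association traces follow $F = \Delta F_{max}(1-e^{-k_{obs}t}) + C$;
dissociation traces follow one or two exponentials. All fits exclude points
before the instrument dead time (default 1.4 ms) rather than attempting
deconvolution — the dead-time transient carries mixing artifacts with no
usable model.

`fitDissociation(model = "auto")` fits both candidates and selects by the
corrected Akaike information criterion (AICc) computed from the residual
sum of squares. Two numerical guards make this robust:

- the RSS entering the AICc is floored at a numerically-zero value
  ($n\,(10^{-9}\,\mathrm{range}(y))^2$), so machine-precision fits of clean
  data are compared by parameter count instead of rounding noise;
- a double fit whose rates agree within 1 % (or whose minor component
  carries < 0.1 % of the amplitude) is degenerate and collapses to the
  single model.

Biexponential starting values come from log-linear peeling: the slow
component is estimated by a linear fit to $\log(F - C)$ over the trailing
40 % of points, then the fast component from the log-residual of the early
points. Rates are reported fast-first with amplitude percentages summing to
100.

The mole-fraction association rate constant is
$k_{on,x} = (k_{obs}-k_{off})\,[\mathrm{H_2O}]/[L]$. Which dissociation
component to subtract (fast, slow, or amplitude-weighted) is not uniquely
determined by the biexponential fit, so `associationRateConstant()` takes
the chosen $k_{off}$ as an explicit argument; the fast component reproduces
the published plasma-membrane value (30 s⁻¹ and 1.0 s⁻¹ at 37.5 μM
accessible lipid give $43\times10^6$ s⁻¹ at two significant figures) and is
the pipeline default, with the choice recorded in the output.

## Membrane-interaction geometry

Coordinate frames (multi-model PDB, parsed with bio3d) carry typed atoms:
protein residues are recognized by standard residue names (including the
CHARMM histidine tautomers HSD/HSE/HSP); everything else is lipid, with
molecule identity given by segment + residue number.

- **Phosphate plane**: unweighted mean z of the lipid phosphodiester
  phosphorus atoms of one leaflet. Leaflets are not labelled in coordinate
  files, so assignment is operational: P atoms above the mean of all P z
  form the upper leaflet, and the protein-facing leaflet is the one whose
  mean P z is nearer the protein center of mass. PIP₂ ring phosphates
  (P4/P5) are excluded from the plane by using only the atom named `P`.
- **COM height and residue depth**: mass-weighted protein COM z minus the
  plane; residue depth is the z of the Cα (or a named side-chain atom)
  minus the plane, negative meaning inserted below the phosphate plane.
- **Loop tips and angles**: a loop tip is the centroid of the Cα atoms of
  three consecutive residues (defaults: E388/A389/K390 for β2–β3,
  G450/R451/F452 for β6–β7, S406/R407/Q408 for β3–β4); the interloop angle
  is measured at the protein COM between COM→tip vectors. Whether the COM
  should use all atoms or Cα only is not specified by the convention the
  angles come from; both are supported (`comAtoms`), all-atom is the
  default, and the difference is within a few degrees — the tolerance used
  wherever the angles are checked.
- **Electrostatic contacts**: a basic residue contacts a lipid molecule
  when its anchor (Lys NZ, Arg CZ, or the His imidazole-ring heavy-atom
  COM — the five ring atoms CG/ND1/CD2/CE1/NE2, tautomer-independent) is
  within the class cutoff (5.0 / 6.3 / 6.1 Å) of **any** headgroup heavy
  atom; multiple atoms of one lipid count once. Headgroup atom lists
  default to CHARMM36 names — phosphodiester outward for PS/PIP₂, glycerol
  backbone outward for PC — and are fully overrideable, since atom naming
  is force-field dependent. Distances use the minimum-image convention in
  x–y when a box is present; z (the bilayer normal) is treated as
  non-periodic. Contact counting is vectorized over headgroup atoms per
  anchor; the test suite proves it equal to a plain all-pairs double loop
  on 50 random fixtures.
- **Windowed statistics**: `contactTimeStatistics()` averages per-residue
  counts over the trailing fraction of the trajectory (default the last
  half, emulating last-100-ns-of-200-ns reporting) or an explicit time
  range; the SD is across saved frames, which is the only basis available
  once frames are the unit of observation.

## Docking-pose site tabulation

Final ligand positions from repeated docking runs are summarized by
single-linkage agglomerative clustering (`stats::hclust`/`cutree`) at a 5 Å
cutoff: clusters are the connected components of the closer-than-cutoff
graph, which matches the visual notion of a contiguous pose cloud and needs
no cluster-count choice. Labels are deterministic (sorted by descending
size, ties by first-seen index). Each cluster is assigned to the named
binding site (center = mean anchor position of its defining residues)
nearest its centroid if within 8 Å, else "other"; fractions are over all
poses and sum to 1 exactly. The 5 Å / 8 Å defaults reflect the ~1.5 Å
spread of a well-defined pose cloud against ≥ 20 Å site separations and
are exposed in the interface and recorded in output; the clustering
algorithm itself was an open design choice, decided here in favor of
single linkage for its determinism and parameter economy.

## Lysine-modification mass calculations

Modification masses are summed from elemental compositions with standard
monoisotopic and average atomic masses. Phosphogluconoylation — the adduct
formed on lysines of strongly cationic surfaces by bacterial
6-phosphogluconolactone during expression — is fixed as C₆H₁₁O₉P (+258.014
monoisotopic / +258.120 average; both round to the +258 Da observed on
intact protein). Phospho (HPO₃) gives +79.966 → +80 Da. Intact-protein
shifts are matched at 1 Da tolerance because deconvoluted intact spectra
are average-mass measurements; both mass scales are reported. Peptide
masses are monoisotopic (residue masses + water + modifications), matching
±20 ppm precursor / ±50 ppm fragment tolerances. Fragment ladders are
singly-charged b and y ions (n−1 each; b = residue sum + proton, y =
residue sum + water + proton), with modifications shifting exactly the ions
containing the modified site. `enumerateSiteAssignments()` encodes the
mutual-exclusion logic: a single +258 Da intact shift admits exactly one
modified site among the cluster lysines.

## Synthetic data: what it emulates, and what it does not

The generators produce the study conditions used throughout validation:

- titrations: 20 points (a zero point plus 19 log-spaced to 20 mM),
  IC₅₀ = 620 μM truth, Gaussian noise at 2 % of amplitude — the
  plasma-membrane-composition regime;
- kinetic traces: 1000 points per shot, 1.4 ms dead time, association
  truth 30 s⁻¹, dissociation truth 1.0/0.14 s⁻¹ at 35/65 % amplitude, 1 %
  noise per shot, 8 replicate shots;
- membrane frames: a planar lipid lattice (8 Å spacing, phosphate planes at
  ±20 Å) with CHARMM-like atom/residue names so production configs work
  unchanged; a pseudo-protein whose COM sits exactly 23 Å above the plane
  (within the 21–25 Å range typical of initial protein–bilayer complexes)
  and whose basic-residue anchors realize a prescribed per-frame contact
  schedule exactly (the lattice guarantees every non-target lipid is > 1
  spacing away, beyond all cutoffs);
- pose clouds: 510 poses from isotropic Gaussian mixtures (sd 1.5 Å,
  centers ≥ 25 Å apart).

Every generator is bit-reproducible per seed (the caller's RNG state is
saved and restored), and the recorded ground truth suffices to compute the
expected output of every analysis operation.

What passing these tests shows: the estimators are unbiased and precise
under Gaussian noise at realistic magnitudes, the geometric metrics are
exact on constructed coordinates and invariant under rigid motion, and the
bookkeeping (contact binarization, ladder additivity, fraction
normalization) is correct. What it does not show: robustness to correlated
instrument noise, photobleaching drifts, spectral lineshapes, force-field
realism of lipid conformations, or detector nonlinearity — none of which
the generators attempt to emulate. Published kinetic and contact tables
from real instruments and trajectories are therefore covered by
regime-matched round-trips and property suites, not reproduced from raw
data.

## Problem sizes and runtime

The test suite runs 100-seed recovery studies for the titration and
biexponential fits, 50 random fixtures for the contact oracle, and
510-pose clustering, completing in well under a minute; the acceptance
script repeats the headline computations at the same sizes. These sizes
were chosen so that Monte-Carlo medians are stable to well within the
tolerances they are tested against.

## Known limitations

- Dissociation model selection considers one or two exponential
  components; stretched or three-component decays are out of scope.
- Binary trajectory formats (DCD/XTC) are not read; frames are exchanged
  as concatenated PDB MODEL records.
- Fragment ions are singly charged; multiply-charged fragment annotation
  is out of scope.
- The competition model assumes a single competitive site and no
  cooperative rebinding; IC₅₀ values near $K_I$ (binding indistinguishable
  from inhibitor affinity) are rejected rather than extrapolated.
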