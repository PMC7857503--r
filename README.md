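# C2MemBind

Quantitative analysis of Ca²⁺-independent membrane binding by polybasic C2
domains.

Peripheral membrane proteins such as the Slp-4 (granuphilin) C2A domain dock
onto the plasma membrane through electrostatic interactions between a
cationic protein surface and anionic lipids — a conserved lysine cluster
selective for PIP₂ plus a broader basic surface that binds background
anionic lipids (PS/PI). Characterizing this binding quantitatively involves
several distinct measurements, each with its own analysis layer. C2MemBind
implements those layers as one tested R package for membrane biophysicists:

- **Equilibrium partitioning from competition titrations.** A
  protein-to-membrane FRET signal F is titrated with a soluble competitor
  (IP₆) and fitted to the single-site competitive-inhibition hyperbola

  F = ΔF_max (1 − [IP₆]/(IC₅₀ + [IP₆])) + C

  The IC₅₀ converts to a mole-fraction partition coefficient and binding
  free energy:

  K_x = (IC₅₀/K_I − 1) · [H₂O]/[L],  ΔG° = −RT ln K_x

  with K_I the protein–IP₆ dissociation constant (1.8 μM), [H₂O] the bulk
  water concentration (55.5 M) and [L] the accessible (outer-leaflet) lipid
  concentration — one-half of the total lipid. Lipid-only and
  buffer-dilution control corrections and unit-amplitude normalization are
  included.

- **Stopped-flow kinetics.** Replicate shots are averaged; association
  traces are fitted to F = ΔF_max(1 − e^(−k_obs·t)) + C and dissociation
  traces to single or double exponentials, with AICc-based model selection
  and a 1.4 ms instrument dead time excluded from fits. The mole-fraction
  association rate constant is k_on,x = (k_obs − k_off) · [H₂O]/[L].

- **Membrane-interaction geometry** from coordinate frames (multi-model
  PDB): the phosphate plane (mean z of lipid phosphorus in the
  protein-facing leaflet), protein center-of-mass height, residue insertion
  depth (negative = inserted), loop-tip positions and interloop angles, and
  per-residue electrostatic lipid contacts (Lys NZ within 5.0 Å, Arg CZ
  within 6.3 Å, His imidazole-ring COM within 6.1 Å of lipid headgroup heavy
  atoms; one count per distinct lipid molecule), with windowed mean ± SD
  summaries.

- **Docking-pose site tabulation**: single-linkage clustering of docked
  ligand positions and occupancy fractions over named binding sites (lysine
  cluster, loops region, other).

- **Lysine-modification mass spectrometry calculations**: modification
  masses from elemental composition (phosphogluconoyl C₆H₁₁O₉P = +258.01
  Da; phospho = +79.97 Da), peptide monoisotopic masses, b/y fragment-ion
  ladders with site-specific mass shifts, and intact-protein mass-shift
  assignment with mutually exclusive site enumeration.

- **Synthetic data generators** for every input type (titration curves,
  kinetic traces, bilayer+protein coordinate frames with analytic ground
  truth, pose clouds), used throughout the test suite.

## Worked example

Fit the packaged example competition titration and convert it to
thermodynamic quantities:

```r
library(C2MemBind)

curve <- readTitrationCsv(system.file("extdata", "synthetic_titration_PM.csv",
                                      package = "C2MemBind"))
fit <- fitCompetitionTitration(curve)
fit
#> CompetitionFit: IC50 = 671.2 +/- 39, dFmax = 1.007, C = -0.02132 (n = 20)

ic50ToPartitionCoefficient(ic50(fit), PartitioningInputs())
#> PartitioningResult: Kx = 3.3e+08 (330 x 1e6), deltaG = -11.62 kcal/mol
```

The IC₅₀ (μM) is the competitor concentration displacing half the initially
bound protein; Kx ≈ 3.3 × 10⁸ means partitioning onto the membrane surface
is favored by ≈ −11.6 kcal/mol at 25 °C. Kinetics work the same way:

```r
sim <- simulateKineticTrace("double", rates = c(1.0, 0.14),
                            amplitudes = c(0.35, 0.65), noiseSd = 0.01,
                            seed = 42)
dfit <- fitDissociation(sim$trace, model = "auto")
dfit
#> DissociationFit (double): 1.03 /s (35% amp), 0.141 /s (65% amp), C = 2.659e-05

associationRateConstant(30, offRates(dfit)[1],
                        PartitioningInputs(accessibleLipid = 37.5))
#> RateResult: kon,x = 4.288e+07 /s (42.9 x 1e6)
```

and the mass-spectrometry layer identifies the lysine adduct behind a
+258 Da intact-protein shift:

```r
pg <- standardModifications()$phosphogluconoyl
modificationMass(pg)
#> monoisotopic      average
#>     258.0141     258.1199
head(fragmentLadder(ModifiedPeptide("SNPYVkTYLLPD", list(k = pg))), 3)
#>   ion series index        mz
#> 1  b1      b     1  88.03931
#> 2  b2      b     2 202.08224
#> 3  b3      b     3 299.13500
```

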