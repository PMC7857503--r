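Package: C2MemBind
Title: Quantitative Analysis of Calcium-Independent C2 Domain Membrane
    Binding
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying peripheral membrane binding of
    polybasic C2 domains. Implements equilibrium competition-titration
    analysis (hyperbolic IC50 fits converted to mole-fraction partition
    coefficients and binding free energies), stopped-flow kinetic fitting
    (single/double exponential association and dissociation with
    AICc-based model selection and mole-fraction association rate
    constants), membrane-interaction geometry from coordinate frames
    (phosphate-plane reference, center-of-mass height, residue insertion
    depth, interloop angles, and per-residue electrostatic lipid-headgroup
    contact counting), docking-pose clustering with binding-site occupancy
    tabulation, and peptide/fragment-ion mass calculations for
    lysine-modification (phosphogluconoylation) identification. A
    synthetic-data module generates titration curves, kinetic traces,
    bilayer-plus-protein coordinate frames and pose clouds with recorded
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, StructuralPrediction, Proteomics, MassSpectrometry
RoxygenNote: 7.3.3
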