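Package: ensembleFE
Title: Ensemble Binding Free-Energy Estimation and Assay Distribution
    Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ensemble-based analysis of binding free energies from
    molecular-dynamics replica simulations. Provides endpoint (MMPBSA-style)
    aggregation of per-frame energies into absolute binding free energies
    with replica-bootstrap uncertainties, thermodynamic integration over a
    fixed lambda schedule for relative binding free energies, conversion of
    assay potencies (pIC50) to free energies with
    calculation-versus-experiment agreement statistics, and descriptive
    characterization of the non-normal, heavy-tailed distributions observed
    in repeated assay measurements. Seed-reproducible synthetic-data
    generators with recorded ground truth make every stage testable without
    trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'sinhArcsinh.R'
    'AllClasses.R'
    'synthetic.R'
    'endpoint.R'
    'alchemical.R'
    'compare.R'
    'diststats.R'
    'io.R'
    'pipeline.R'
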