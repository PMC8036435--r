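Package: fieldqsar
Title: Grid-Based 3D-QSAR with Force-Field and Gaussian Molecular
    Interaction Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Field-based three-dimensional quantitative
    structure-activity relationship (3D-QSAR) modelling for rigid,
    mutually aligned small-molecule series. Computes probe interaction
    fields (Lennard-Jones steric and Coulomb electrostatic with a
    distance-dependent dielectric) and Gaussian similarity fields
    (steric, electrostatic, hydrophobic, hydrogen-bond donor and
    acceptor) on a rectilinear lattice, filters grid variables, and
    links them to pEC50 activities by NIPALS partial least squares with
    leave-one-out cross-validation, y-scrambling, subsampling stability,
    per-field contribution fractions and an exhaustive field-combination
    scan. Includes external validation (predictive R2 and the
    Golbraikh-Tropsha acceptability criteria), coefficient contour-map
    extraction with OpenDX export, rule-based drug-likeness filters
    (Lipinski, Ghose, Veber, Egan), and a synthetic aligned-series
    generator with a planted field-space activity model for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, ChemmineR, jsonlite
Suggests: testthat (>= 3.0.0)
SystemRequirements: Open Babel (obabel on the PATH) for fallback
    partial-charge assignment and physicochemical descriptors
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'chem-io.R'
    'grid.R'
    'fields.R'
    'pls.R'
    'contours.R'
    'druglikeness.R'
    'synthetic.R'
    'validation.R'
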