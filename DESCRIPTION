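Package: polypflow
Title: Quasi-Steady Stokes Simulation of Periderm-Dwelling Polyp Pumping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Prescribed-kinematics simulation of suspension feeding by a
    millimetre-scale benthic polyp enclosed in a rigid periderm. The package
    builds a parametric axisymmetric stand-in for the fossil-derived body
    form, drives rhythmic expansion/contraction of the bowl-shaped
    subumbrella through a spline amplitude profile and smooth temporal
    ramps, solves the quasi-steady incompressible creeping-flow (Stokes)
    equations on a staggered grid with volume penalization of the moving
    boundary, and derives the observables of interest for benthic
    suspension-feeding hydrodynamics: velocity time series at axial sampling
    points above the peridermal aperture, per-scenario velocity maxima,
    azimuthal vorticity fields with vortex-core tracking, Reynolds numbers,
    and grid-sensitivity reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
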