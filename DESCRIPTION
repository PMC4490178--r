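Package: vtfem
Title: Vocal-Tract Acoustics by Finite-Element Helmholtz Models with
    Impedance Boundary Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes vocal-tract transfer functions by solving the 3D
    Helmholtz equation with the finite-element method on tagged tetrahedral
    meshes of tract-like air cavities. Complex specific impedance boundary
    conditions represent sound radiation at the mouth opening (half-sphere,
    baffled rigid piston, or its low-frequency approximation) and a lumped
    mass-damper model of the yielding tract wall. Formant frequencies and
    half-power bandwidths are extracted from the simulated transfer
    functions, and measured formant tables can be inverted into
    frequency-dependent areal wall-impedance parameters by sampling the
    (mass, damping) plane, fitting bilinear objective surfaces, and
    intersecting their level curves analytically. A one-dimensional
    transmission-line solver for stacked uniform cylinders serves as an
    independent cross-check of the 3D models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
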