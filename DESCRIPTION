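Package: pdlvisco
Title: Fractional Viscoelastic Model of the Periodontal Ligament
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical continuum model of a nearly incompressible
    viscoelastic periodontal ligament (PDL) surrounding an
    elliptic-paraboloid tooth root.  Provides the root/PDL geometry with
    surface quadrature, rigid-root kinematics and PDL strain fields, the
    Rabotnov fractional-exponential creep/relaxation kernel with series
    truncation control, assembly of the rigid-root stiffness coefficients
    by surface quadrature, closed-form and numerical (Volterra
    product-integration) translational creep solutions, inverse force
    solving, and hydrostatic stress maps over the root surface.  Includes
    a reference parameter set for a human incisor and command-line entry
    points for stiffness, creep, stress-map and force computations.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
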