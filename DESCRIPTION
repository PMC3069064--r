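Package: ciliasim
Title: Immersed-Boundary Simulation of Inner Hair Cell Stereocilia Bundle
    Hydrodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional immersed-boundary fluid-structure simulator of
    the inner hair cell stereocilia bundle in the subtectorial space. The three
    stepped stereocilia rows, their tip links with threshold gating springs and
    their horizontal top connectors are represented as elastic Lagrangian point
    chains coupled to an incompressible Navier-Stokes solver (Chorin projection
    on a staggered grid) through a regularized four-point delta kernel. Boundary
    motion emulates the orbital oscillation of the reticular lamina at 200 Hz
    with a vertically co-moving tectorial membrane and analytic oscillatory
    Stokes-layer side conditions. Diagnostics extract tip-link stretch versus
    drive phase, per-row rotation and length-change kinematics, closed-contour
    nanovortex detection, and closed-form estimates for calcium transport
    (diffusive supply rate, Rayleigh vorticity of a suddenly elongating gating
    spring, and the critical elongation time).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
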