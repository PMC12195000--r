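Package: memphase
Title: Curvature-Composition Coupling in Multicomponent Fluid Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the generalized Helfrich free energy of multicomponent
    fluid membranes. Provides composition-dependent curvature elasticity with
    linear mixing of bending rigidity, Gaussian rigidity and tension, a
    Ginzburg-Landau double-well potential, parametric surface patches (sphere,
    cylinder, surfaces of revolution) carrying metric and curvature data, two
    discrete Laplace-Beltrami operators (the intrinsic one and the
    Gaussian-curvature-weighted one), pointwise Euler-Lagrange residuals of the
    coupled curvature-composition equilibrium equations, closed-form and
    numeric equilibrium radii for spherical and cylindrical vesicles, a 1D
    kink solver for interface width and line tension, gradient-flow relaxation
    of the composition field on fixed geometries, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
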