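Package: cardiogrowth
Title: Finite-Growth Simulation of Concentric and Eccentric Cardiac Hypertrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static nonlinear finite-element simulation of stress-driven
    cardiac growth and remodeling. Implements the multiplicative elastic/growth
    decomposition of the deformation gradient with transverse (concentric,
    parallel sarcomere deposition) and longitudinal (eccentric, serial
    sarcomere deposition) growth tensors, stretch-driven growth kinetics with
    a locally calibrated homeostatic fiber-stretch threshold, and a
    quasi-incompressible orthotropic Fung-type myocardium model. Ships a
    parameterized truncated-ellipsoid left-ventricle mesh generator with
    rule-based helical fiber architecture, follower (pressure) loads, a Newton
    solver with staggered equilibrium/growth stepping, and scenario drivers
    that reproduce the organ-level phenomenology of pressure- and
    volume-overload hypertrophy: wall thickening with saturation, progressive
    dilation, and compliance shifts in the pressure-volume relation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    xml2
Config/testthat/edition: 3
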