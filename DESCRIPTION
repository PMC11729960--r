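Package: porolung
Title: Reduced-Order Poroelastic Lung Inflation and Inverse Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale, five-lobe poroelastic model of positive-pressure
    lung inflation and the inverse-analysis machinery to calibrate it against
    ventilation experiments. The parenchyma is an Ogden-type compressible
    hyperfoam, embedded airways are a Neo-Hookean volumetric surrogate, and
    the pleura is an incompressible reduced-polynomial membrane closed by a
    Laplace law. Tracheal pressure drives permeability-limited airflow into
    spherical lobe compartments; the package produces pressure-volume curves
    and lobe-wise major-strain statistics, fits pleura equibiaxial data,
    checks material convexity, and calibrates the material parameters by
    bounded nonlinear least squares with multistart and an explicit
    five-criterion termination protocol. Synthetic experiment generators with
    known ground truth make every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
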