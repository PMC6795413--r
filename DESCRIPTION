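Package: dualvar
Title: Dual-Number Tangent Linear and Adjoint Models for Variational
    Data Assimilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-mode automatic differentiation with dual numbers
    (single and multiple independent dual parts) that turns evaluations of
    a nonlinear model into exact tangent linear and adjoint model products.
    Includes a reduced-cost segmented adjoint that exploits the per-grid-cell
    locality and restricted variable footprints of biogeochemical process
    segments, an eleven-variable NEMURO-type plankton ecosystem column model
    as a realistic differentiation target, an incremental strong-constraint
    4D-Var minimizer built on the tangent linear and adjoint sweeps, and a
    twin-experiment driver with synthetic dense and cloud-masked observation
    streams. Adjoint consistency is verifiable through built-in dot-product
    and Taylor-remainder tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
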