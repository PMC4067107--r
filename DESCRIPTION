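Package: afmvisc
Title: Transient Viscoelastic Analysis of AFM Nanoindentation Force Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of atomic force microscopy (AFM) nanoindentation
    force curves for soft nanomaterials whose response is both adhesive
    and viscoelastic. Implements an adhesive (DMT) spherical contact
    model extended to a standard linear solid (Zener) material by the
    functional-equation (elastic-viscoelastic correspondence) method:
    closed-form force relaxation under a step approach, indentation
    depth creep under a step force, uniaxial stress relaxation and
    strain creep, and storage/loss shear moduli. Extracts the model
    parameters (two elastic moduli and a viscosity) from force-time
    relaxation curves by a three-point solve or damped nonlinear least
    squares, and the instantaneous modulus from DMT loading curves.
    Includes a seeded synthetic-curve generator, numerical
    inverse-Laplace oracles, tidy accessors, plotting helpers and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
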