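Package: sasri
Title: Modified Guinier Analysis of Small-Angle Scattering Concentration
    Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting interparticle-interaction information
    from the low-Q asymptotic behaviour of small-angle neutron or X-ray
    scattering data. From a concentration series of reduced 1D profiles
    the package performs classical Guinier fits, extracts the second
    osmotic virial coefficient B22 from the forward-scattering series,
    and applies a modified Guinier analysis to obtain the
    infinite-dilution radius of gyration and the model-independent
    radius of interparticle interaction. Companion routines compute the
    interaction radius and B22 from isotropic pair potentials by
    quadrature, evaluate classical and modified Zimm forms, and simulate
    synthetic concentration series with counting-statistics noise.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
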