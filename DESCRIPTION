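Package: asciflow
Title: Ascitic Currents and Ovarian Wall Shear Stress from Diaphragmatic Excursion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element simulation pipeline for breathing-driven ascitic
    fluid currents in the peritoneal cavity and the fluid shear stress (FSS)
    they impose on ovarian wall patches, together with the companion
    perfusion-bioreactor shear model used to translate ascitic FSS levels
    into in vitro operating points. Provides synthetic cavity and channel
    mesh generators with tagged boundary patches, an isovolumetric
    diaphragm-forcing model with linear-elastic mesh motion, an arbitrary
    Lagrangian-Eulerian incompressible Navier-Stokes solver (Taylor-Hood and
    stabilized equal-order elements), consistent-flux wall shear stress
    extraction with per-patch cycle metrics, a Brinkman hydrogel plug model
    with an idealized-cell open-channel submodel and inverse design of pump
    operating points, and a verification suite against classical closed-form
    flows (plane Poiseuille, Womersley, Stokes flow past a sphere).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
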