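Package: rwvsim
Title: Coupled Fluid, Transport, and Growth Simulation of Cross-Feeding
    Microbial Communities in Microgravity, Rotating-Wall Vessels, and 1 g
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator of a two-species, obligately cross-feeding
    bacterial community (a methionine-auxotrophic Escherichia coli and an
    acetate-consuming, methionine-secreting Salmonella enterica) in three
    physical regimes: spaceflight microgravity, rotating-wall-vessel (RWV)
    artificial microgravity, and normal 1 g gravity. The model couples
    creeping-flow fluid dynamics in a rotating reference frame (with solutal
    Boussinesq buoyancy), Lagrangian cell motion under Stokes drag,
    centrifugal, Coriolis, and gravity-buoyancy accelerations,
    advection-diffusion of three metabolites (lactose, methionine, acetate)
    on a structured parcel grid, and mass-transfer-limited Monod growth with
    zero-order cross-feeding conversion, with the cell mass-transfer
    coefficient obtained from an empirical Sherwood-number correlation.
    Includes programmatic scenario generators, steady-state growth detection,
    analysis metrics, and CSV/VTK/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
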