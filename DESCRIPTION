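Package: losmodel
Title: Kinetic Modelling of Leukotriene A4 and 5-oxoETE Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A mechanistic kinetic simulator of the 5-lipoxygenase (5-LO)
    pathway in leukocytes: quasi-steady-state rate laws for 5-LO (substrate
    inhibition, pseudo-peroxidase redox cycling, calcium modulation, redox
    and non-redox inhibitor binding), cytosolic phospholipase A2, glutathione
    peroxidase and 5-hydroxyeicosanoid dehydrogenase, assembled into an ODE
    model of arachidonic acid, 5-HPETE, 5-HETE, leukotriene A4 and 5-oxoETE
    dynamics. Provides time-course and steady-state simulation, inhibitor
    dose-response analysis (IC50/IC80 across oxidative-stress levels), a
    Hooke-Jeeves parameter-fitting layer with synthetic-data generation, and
    SBML Level 3 export.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
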