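Package: quasarkin
Title: Thermal Isomerization and Deprotonation Kinetics of the Voltage
    Sensor QuasAr1 from Attenuation Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the dark, room-temperature degradation
    kinetics of the Archaerhodopsin-3 based fluorescent voltage indicator
    QuasAr1. Converts transmission measurements to attenuation coefficient
    spectra, removes the power-law (Rayleigh/Mie) aggregation-scattering
    background fitted in the protein's transparency window, decomposes the
    resulting absorption spectra into retinal Schiff base component bands,
    simulates the two-branch isomerization/deprotonation reaction scheme as
    a first-order ODE system with exponentially relaxing time constants,
    and estimates the ten kinetic parameters by global multi-start weighted
    least squares. A synthetic-data generator emulates the measured spectra
    so the full pipeline runs end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
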