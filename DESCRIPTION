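Package: eisgrowth
Title: Impedance-Based Monitoring of Bacterial Growth and Lead Biorecovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for monitoring bacterial growth in bioreactors from
    electrochemical impedance spectroscopy (EIS) sweeps. Fits a
    fractional-exponent Laplace-domain reactance model (constant offset,
    fractional supercapacitor, Warburg diffusion element, and series
    inductance) to measured impedance spectra by linear and nonlinear least
    squares, aggregates equivalent-circuit parameters across replicate
    reactors and culture time, correlates the extracted supercapacitance
    with plated colony-forming-unit counts during exponential growth, and
    classifies the presence of Pb(II) from the supercapacitor magnitude.
    Includes a synthetic-experiment generator with known ground truth so
    the complete analysis chain can be exercised without laboratory data.
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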