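Package: hingeforce
Title: Force and Free-Energy Analysis for DNA Origami Hinge Force Spectrometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-mechanics analysis of nanoscale DNA force
    spectrometers (nDFS): DNA origami hinges whose per-particle angle
    ensembles, measured from electron micrographs, are converted by
    Boltzmann inversion into free-energy landscapes, torque profiles and
    polar force maps with bootstrap uncertainties.  Includes closed-form
    polymer statistics (Gaussian chain and the stiff-polymer worm-like-chain
    end-to-end distribution), a spherical-grid coupling model predicting the
    angle distribution of a hinge with an incorporated polymer sample and
    the compressive force it bears, a nucleosome-unwrapping partition
    function over tangent-line spool geometry, an Euler elastica
    post-buckling force solution, and synthetic-data generators emulating
    TEM-derived angle ensembles for every device variant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
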