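Package: kinetotrack
Title: Simulation and Quantification of Kinetochore Motility on Dynamic Microtubules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how reconstituted budding-yeast kinetochores
    move along dynamic microtubules. Provides a stochastic simulator of the
    two-state (run/pause) lateral transport model with irreversible
    lateral-to-end-on conversion and tip-coupled depolymerization, a synthetic
    multi-channel kymograph renderer (Gaussian point-spread function, Poisson
    noise, fluorophore blinking), track extraction and run/pause segmentation
    with a resolution-based slope threshold, state-resolved velocity, run
    length and time-fraction statistics, two-channel colocalization scoring
    with a blinking reference, a bilobed/declustered spindle line-scan
    classifier, and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
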