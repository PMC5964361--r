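Package: cuffsep
Title: Separability Analysis of Multichannel Nerve-Cuff Electroneurography
Version: 0.1.0
Authors@R:
    person("ENG", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for afferent electroneurography
    (ENG) recorded with multi-contact nerve cuffs during mechanical stimulation
    of the hindpaw. Provides a forward simulator of fascicular sources mixed
    onto point- and ring-contact cuff electrodes, FIR bandpass preprocessing,
    stimulus-evoked trial segmentation from event markers or a force-sensor
    trace, mean-absolute-value feature extraction, linear discriminant analysis
    with stratified balanced five-fold cross-validation, exhaustive
    electrode-pair search, and paired comparisons between cuff designs
    (3- vs 16-channel) and implantation sites (distal vs proximal).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    yaml,
    withr
Config/testthat/edition: 3
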