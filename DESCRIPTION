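Package: retroshine
Title: Pupil Eyeshine Decomposition and Receptor-Noise Camouflage Modelling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing daytime pupil eyeshine in cryptobenthic
    fishes such as the black scorpionfish (Scorpaena porcus). Decomposes
    measured pupil radiance into stratum-argenteum-reflected (SAR, narrow-
    and broad-sense) and pigment-epithelium-transmitted (PET) eyeshine
    components, fits the dark-adaptation decay of pupil reflectance with a
    gamma log-link GLM and simulation-based credible intervals, forward
    reconstructs field pupil and iris radiances from laboratory component
    spectra and underwater illuminants, and evaluates pupil camouflage from
    a prey fish's perspective with a receptor-noise-limited chromatic model
    and double-cone achromatic Michelson contrasts. Includes a seeded
    synthetic generator for underwater light fields, component spectra,
    field-style measurements and dark-adaptation series, plus a
    config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    MASS,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
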