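Package: npsid
Title: Identification of New Psychoactive Substances by Accurate Mass and
    Infrared Library Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational identification of new psychoactive
    substances (NPS) and their metabolites from high-resolution accurate-mass
    spectrometry and solid-deposition GC-FTIR data. Provides elemental-formula
    parsing and algebra with exact (monoisotopic) mass computation, isotope
    pattern simulation by multinomial convolution with relative isotopic
    abundance (RIA) filtering, elemental composition search within a ppm
    window, biotransformation-based phase I/II metabolite annotation against
    centroided peak tables using a five-criteria evidence model, and infrared
    spectral library matching by first-derivative correlation for positional
    isomer discrimination, including multi-deposition co-addition and limit of
    identification estimation. Ships seeded synthetic-data generators for both
    MS peak tables and IR libraries so every pipeline stage can be exercised
    against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
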