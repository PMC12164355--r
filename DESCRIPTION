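Package: plasmiso
Title: Nanoplasmonic Isosbestic Analysis of Gold Nanoparticle Clustering
    on Soft Templates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of nanoplasmonic
    isosbestic points arising when gold nanoparticles cluster on soft
    templates such as liposomes and extracellular vesicles. Provides gold
    optical constants, Mie cross sections for isolated nanospheres, a
    coupled-dipole solver for cluster extinction spectra, detection of
    isosbestic wavelengths in spectral families, sigmoidal calibration of
    the isosbestic wavelength against interparticle spacing and membrane
    stiffness (with inversion and error propagation), small-angle X-ray
    scattering analysis with a Schulz-polydisperse sphere form factor and
    Baxter sticky-hard-sphere structure factor, and synthetic-data
    generators with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
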