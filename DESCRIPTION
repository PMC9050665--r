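Package: cortimap
Title: Afferent-Density Simulation of Visual Cortical Map Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the formation of multi-dimensional visual cortical maps
    from the density of thalamic afferents sampling visual space. Generates
    jittered ON/OFF retinal ganglion cell mosaics for both eyes, sorts the
    thalamic afferents in the cortical subplate by retinotopy, eye input and
    ON-OFF polarity with difference-of-Gaussians sorting filters, spreads
    thalamocortical axon arbors with ON-OFF synaptic competition, and matures
    the resulting primordial orientation map through orientation-coverage
    optimization, binocular matching and experience manipulations (monocular
    deprivation, orientation bias). Includes the accompanying map statistics
    (circular variance, local homogeneity index, SF50, low-pass index, ocular
    dominance index, pinwheel detection, map periodicity, gradient
    intersection angles, FFT pattern similarity, simulated-track screening)
    and the electrophysiology track-analysis formulas (von Mises orientation
    fits, difference-of-Gaussians spatial-frequency fits, ON-OFF balance,
    recording-quality filters).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
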