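Package: spectraldiv
Title: Spectral Diversity of Grassland Quadrats from Multispectral Radiance Moments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates plant biodiversity in 1x1 m grassland quadrats from
    uncalibrated multispectral radiance images. Computes distributional
    moments (coefficient of variation, standard deviation, skewness,
    kurtosis) of per-band digital-number distributions, in situ biodiversity
    indices (richness, Shannon-Weiner, Simpson) from botanical survey
    tables, and links the two with Bayesian hierarchical regression models
    including quadrat-level random intercepts, PSIS-LOO model comparison,
    and repeatability (intraclass correlation) estimates. A synthetic
    multispectral scene generator emulates species-specific spectral
    signatures, solar-gain noise, and height-dependent pixel smoothing for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    tiff,
    class,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
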