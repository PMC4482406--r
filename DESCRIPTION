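Package: moorweb
Title: Mooring Time-Series Analysis of Bering Sea Spring-Summer Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing moored-observatory records of the southeastern
    Bering Sea shelf across the spring-summer transition: conditioning of hourly
    hydrographic, ice, and chlorophyll fluorescence series onto a daily grid
    (Lanczos-squared low-pass, block averaging, gap interpolation), seawater
    density anomaly and stratification phenology (ice-retreat, thin-ice, and
    stratification-onset dates), a mean/standard-deviation rescaling correction
    for mis-scaled fluorometer records, theoretical multifrequency scattering
    signatures for zooplankton and resonant scatterers via a stochastic
    distorted-wave Born approximation, dB-difference classification of volume
    backscatter into scatterer communities, normalized lagged cross-covariance
    across all measured variables, and between-year environmental dissimilarity
    testing with hierarchical clustering, similarity-profile (SIMPROF)
    permutation tests, and nonmetric multidimensional scaling. A synthetic-data
    generator produces complete mooring years with planted physics, blooms, and
    scatterer composition so that every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    readxl,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
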