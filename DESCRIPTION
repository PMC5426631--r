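Package: tidalflux
Title: Multi-Scale Temporal Analysis of Fish Passage at Tidal Energy Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-term hydroacoustic fish-count time
    series collected in tidal channels. Builds hourly fish-passage series
    from exported echosounder fish tracks, fills deployment gaps by local
    harmonic regression with residual-matched noise, decomposes the series
    with a Morlet continuous wavelet transform tested against simulated
    white noise, fits a tidal-constituent harmonic model to fish swimming
    directions to predict tidal stage, and summarises counts by tidal stage
    and diel period. Includes a synthetic-data generator that reproduces
    the statistical structure such analyses assume (planted tidal, diel,
    spring-neap and seasonal periodicities under a Poisson count model,
    square-wave fish headings, and a realistic deployment gap calendar).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
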