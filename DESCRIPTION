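Package: petrelcall
Title: Bioacoustic Indices of Population Size and Breeding Success for
    Burrow-Nesting Storm Petrels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for passive acoustic monitoring of burrow-nesting storm
    petrel colonies. Simulates colonies of nests along stone walls together
    with their nightly calling behaviour, playback responses and breeding
    outcomes; synthesizes and detects the three diagnostic call types
    (adult purr, adult chat, chick beg) in 16 kHz audio; turns detections
    into nightly call-rate series with moon and wind filtering and an
    accumulation-curve stability criterion; estimates plot population size
    (apparently occupied nests) from repeated playback surveys with a
    detection correction and bootstrap confidence intervals; and fits the
    comparative models linking acoustic indices to observer-based measures
    of abundance and breeding success (Poisson and binomial GLMs with
    AIC-based polynomial selection, and a chick-age smooth with random
    intercepts and AR(1) residuals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
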