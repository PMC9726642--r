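Package: piezoprod
Title: Hydrostatic Pressure Effects on Deep-Sea Prokaryotic Heterotrophic Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for deep-sea microbial activity studies that
    compare incubations under in situ hydrostatic pressure with depressurized
    (atmospheric pressure) incubations. Converts scintillation counts from
    3H-leucine radiotracer incubations into bulk leucine incorporation rates,
    fits a depth power law describing pressure inhibition of community
    activity, converts microautoradiography silver-grain halo areas into
    single-cell leucine uptake rates, decomposes the active community into
    piezotolerant, piezosensitive and piezophilic fractions from paired
    activity histograms with minimum/maximum abundance bounds, and balances a
    depth-resolved prokaryotic carbon demand against the particulate organic
    carbon supply from sinking flux. A synthetic-data module emulates the
    measurement structure of such studies so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
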