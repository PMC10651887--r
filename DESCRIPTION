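Package: seagrassN15
Title: Stable-Isotope Tracer Analysis of Seagrass-Holobiont Nitrogen Cycling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 15N amino-acid tracer incubations of
    seagrass and seawater. Provides isotope-notation arithmetic and
    pool-mixing mass balances, a forward simulator of bottle incubations
    with labelled-nitrogen transfer from dissolved free amino acids through
    ammonium into plant tissue and particulate organic matter, source-sink
    estimators of ammonification and atom-percent-excess nitrogen uptake
    rates, oxygen-to-carbon rate conversion and benthic-pelagic
    amplification factors, and functional screening of
    metagenome-assembled genomes (quality tiers, EC-wildcard matching and
    metabolic-module completion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
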