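Package: ardra
Title: In Silico ARDRA and a 463 bp PCR Marker System for Aerobic
    Endospore-Forming Bacilli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational reimplementation of a PCR/restriction marker system
    for aerobic endospore-forming bacilli (AEFB): in silico HaeIII digestion of
    16S rRNA genes with gel-like band binning, mismatch-tolerant primer-site
    search and in silico PCR for the 463F/463R primer pair, extraction and
    screening of the ~463 bp diagnostic marker, generalized diagnostic-fragment
    discovery for arbitrary target/outgroup sets with a simplified conserved
    window primer designer, and marker-based neighbor-joining trees. Ships a
    deterministic synthetic 16S-like sequence generator so every analysis is
    testable without downloads, plus an 'ardra' command-line tool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
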