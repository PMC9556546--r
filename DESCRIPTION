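Package: meiocross
Title: Meiotic Crossover Patterning by HEI10 Coarsening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates class I meiotic crossover designation in Arabidopsis
    by a coarsening model in which the pro-crossover protein HEI10 diffuses
    along the synaptonemal complex and is exchanged with discrete foci, so
    that a few large, well-spaced crossover-promoting foci emerge.  Provides
    the companion analysis pipeline: crossover-interference statistics
    (inter-crossover distance distributions with a permutation null,
    coefficient-of-coincidence curves, crossover density profiles and count
    summaries), sliding-window crossover calling from backcross
    marker-genotype matrices with sample quality control, depth-based
    aneuploidy screening, and synthetic-data generators that emulate
    backcross sequencing populations so every stage can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
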