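Package: trigamete
Title: Three-Point Gamete Frequency Estimation and Linkage Mapping in F2 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the frequencies of three-locus gamete classes in F2
    intercross populations and turns them into recombination fractions and
    marker orders. Implements an iterative expectation-least-square (ELS)
    estimator for dominant markers, whose repulsion-phase pairs carry almost
    no two-point linkage information, and a closed-form binomial analysis of
    three-point gametes (BAT) for codominant markers. Gamete frequencies are
    normalized, linkage phase and within-triple order are inferred from the
    parental and double-crossover classes, pairwise recombination fractions
    are averaged over reference loci, and multi-locus maps are ordered by
    minimizing the sum of adjacent recombination fractions. A standard
    two-point EM estimator and an F2 meiosis simulator with Haldane map
    distances are included for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
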