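Package: strengthnet
Title: Weighted and Binary Network Analysis of Directed Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the contribution of connection strength to the
    topology and simulated function of directed, weighted connectomes
    reconstructed from retrograde tract tracing. Provides weight transforms
    (log labeled-neuron counts, extrinsic fraction of labeled neurons),
    directed binary and weighted clustering and characteristic path/step
    lengths, degree- and in-strength-preserving rewiring and weight-shuffling
    null ensembles with empirical p-values and false-discovery-rate control,
    directed Leicht-Newman modularity with Rand-index comparison, binary and
    weighted rich-club analysis over an external in-degree, an evolutionary
    Pareto morphospace sampler for small-world trade-offs, and Kuramoto
    oscillator simulations with module and rich-club synchrony statistics.
    Includes a synthetic connectome generator emulating the statistical
    structure of dense tract-tracing data so every stage can be exercised
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
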