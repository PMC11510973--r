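Package: wplinet
Title: Functional Brain Networks and Multimodal Graph Classification from
    EEG and fNIRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Builds weighted phase lag index (WPLI) functional brain
    networks from multichannel EEG and fNIRS cerebral-oxygen-exchange
    recordings, derives graph-theoretic summaries (node degree, clustering
    coefficient, global and local efficiency, normalized betweenness,
    small-world index), and classifies motion-sickness state with a graph
    convolutional network over fused bimodal graphs with TopK pooling.
    Ships a synthetic signal generator that plants known phase-lag
    coupling structure so every stage of the pipeline is testable end to
    end without access to recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
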