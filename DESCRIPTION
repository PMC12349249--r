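Package: enosefs
Title: Few-Shot Metric Learning for Electronic-Nose Gas Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end few-shot classification of multichannel gas-sensor
    time series, aimed at breath-based disease screening with very few
    labelled samples per class. Provides sensor-array signal preprocessing
    (per-second averaging, window truncation, equal-interval extraction,
    per-channel min-max normalisation, channel-shuffle augmentation),
    mutual-information sensor ranking from static and dynamic response
    features, N-way K-shot episode construction, a squeeze-and-excitation
    relation network with residual convolutional embedding and a
    bidirectional GRU similarity head (trained episodically with an MSE
    relation loss and Adam), Siamese and prototypical baselines, evaluation
    statistics with t-distribution confidence half-widths, and a seeded
    synthetic gas-response generator so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
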