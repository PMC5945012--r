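Package: circatissue
Title: Circadian Rhythm Detection and Inter-Tissue Rhythm Comparison for
    Expression Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects 24-hour rhythmic genes in multi-tissue expression time
    series with a nonparametric cosine-ordering test (Jonckheere-Terpstra /
    Kendall S against phased reference waveforms, exact null distribution,
    Bonferroni across phases and Benjamini-Hochberg across genes), and
    quantifies inter-tissue rhythm variability: circular phase lags, percent
    amplitude differences, circular phase correlation, multi-set overlap
    partitions, and functional-group phase structure. Includes a two-step
    median/mean normalization for microarray intensity matrices and a
    synthetic multi-tissue generator with known rhythmic ground truth for
    end-to-end validation.
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
    yaml
Config/testthat/edition: 3
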