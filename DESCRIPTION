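Package: acumine
Title: Acupoint-Pattern Association Mining from Curated Case Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for curated acupuncture case records from
    classical East Asian medical texts. Each case pairs the acupoints
    prescribed for a disorder with the diagnostic patterns implicated for
    it. The package builds the acupoint-by-pattern case-level co-occurrence
    matrix, weights it by term frequency-inverse document frequency in both
    directions (patterns characterizing acupoints and acupoints
    characterizing patterns), cosine-normalizes the weight vectors, links
    acupoints whose profiles lie within a correlation-distance threshold,
    extracts connected-component modules with their hub points, and reports
    ranked association tables, module mean profiles, heatmaps and radar
    charts. A synthetic-corpus generator with planted acupoint-pattern
    modules supports validation when the underlying curated corpus is not
    available.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    igraph,
    ggplot2,
    e1071,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
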