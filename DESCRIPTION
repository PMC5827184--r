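Package: cdslm
Title: Prediction-Based Neural Language Models of Semantic Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: From-scratch simple recurrent network (SRN), long short-term
    memory (LSTM) and skip-gram language models trained on child-directed
    speech with an age-ordered, locally iterated training regime, plus the
    analysis stack used to probe what semantic structure such models
    acquire: contextual-representation extraction by hidden-state averaging,
    probe-word similarity matrices, inter-model reliability,
    balanced-accuracy semantic classification via a signal-detection
    threshold sweep, category-level similarity structure with hierarchical
    clustering, and principal-component analysis of hidden units. Includes a
    synthetic child-directed-speech generator with planted semantic
    categories, Zipfian word frequencies and injectable polysemy, so the
    whole pipeline is testable without any external corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
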