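Package: hippoval
Title: Rapid Binding of Exteroceptive Patterns to Emotional Valences in a
    Hippocampal Associative-Memory Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time simulation of single-trial binding between sparse
    exteroceptive activity patterns and interoceptive valence codes, built
    from interconnected binary Willshaw associative memories with clipped
    Hebbian synapses. Intermediate valence cells are organised into ordered,
    mutually inhibiting groups that detect valence-overload interference
    (one cue linked to contradictory valences) and resolve it by recruiting
    a successive group, without unlearning. Includes two comparison models
    (a flat concatenated autoassociative memory and a reduced
    heteroassociative model), generators for all synthetic stimuli, a
    cue/context reversal-learning task, and block/trial experiment drivers
    with confidence-interval summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
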