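Package: kmr
Title: Knowledge-Oriented Multimodal Drug Representations for Interaction
    and Similarity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns fused drug representations from three knowledge sources:
    IDF-weighted pharmacological attribute vectors (side effects, drug
    actions, physiological effects, formulations, targets) plus substructure
    fingerprints reduced by a convolutional encoder; drug-class taxonomy
    embeddings from DeepWalk-, node2vec- and LINE-style network embedding
    channels fused by a multi-channel convolution; and Bi-LSTM encodings of
    dependency-parsed drug descriptions with word- and sentence-level
    attention.  The three blocks are reweighted by an interactive attention
    mechanism and concatenated into a single drug vector feeding a softmax
    head for drug-drug interaction classification and a random-forest head
    for drug-drug similarity regression.  Includes a synthetic knowledge-base
    generator with planted cluster structure so the full pipeline is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
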