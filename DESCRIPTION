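Package: bacner
Title: Bacterial Named Entity Recognition with a BiLSTM-CRF and Domain Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid sequence-labelling framework for recognising bacterial
    names in biomedical text. Per-token representations concatenate word
    embeddings, character-level convolutional features, part-of-speech
    embeddings and gazetteer (dictionary) embeddings; a bidirectional LSTM
    encodes the sentence and a linear-chain conditional random field decodes
    IOB2 tag sequences via Viterbi. Includes a CoNLL-style corpus reader and
    writer, a bidirectional maximum-matching gazetteer tagger, strict
    span-level precision/recall/F1 evaluation, a mini-batch Adam training
    loop with dropout and early stopping, and a seeded synthetic-corpus
    generator so the whole pipeline is testable without external data.
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
    jsonlite
Config/testthat/edition: 3
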