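Package: chvmine
Title: Consumer Health Vocabulary Mining with Supervised Embedding
    Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semiautomatic mining of consumer health vocabularies from
    health-forum text. Word embeddings are pretrained on a tokenized
    corpus, adapted by a trainable low-rank projection matrix fitted with
    a ranking-based surrogate loss on seed pairs of professional and
    consumer terms, and used to rank candidate consumer terms for each
    professional term. Includes corpus preprocessing, compact reference
    trainers for CBOW, skip-gram, GloVe and subword (fastText-style)
    embeddings, mean-reciprocal-rank evaluation, an entropy-based
    detector for consumer terms lacking any professional counterpart,
    a synthetic-corpus generator with planted synonym structure, and a
    command-line interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
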