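#' @include AllClasses.R
NULL

#' Extract the tokenized messages of a corpus
#' @param x a [Corpus].
#' @return list of character vectors.
#' @export
setGeneric("messages", function(x) standardGeneric("messages"))

#' Source label of a corpus
#' @param x a [Corpus].
#' @return character scalar.
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))

#' Tokens of a vocabulary, in id order
#' @param x a [Vocabulary] or an object carrying one.
#' @return character vector.
#' @export
setGeneric("vocabTokens", function(x) standardGeneric("vocabTokens"))

#' Corpus frequency of tokens
#' @param x a [Vocabulary] or an object carrying one.
#' @param tokens character vector; default all tokens.
#' @return named integer vector of counts (0 for absent tokens).
#' @export
setGeneric("tokenFreq", function(x, tokens = NULL) standardGeneric("tokenFreq"))

#' Integer id (1-based) of tokens in a vocabulary
#' @param x a [Vocabulary] or an object carrying one.
#' @param tokens character vector.
#' @return integer vector; NA for tokens not in the vocabulary.
#' @export
setGeneric("tokenIndex", function(x, tokens) standardGeneric("tokenIndex"))

#' Number of tokens in a vocabulary
#' @param x a [Vocabulary] or an object carrying one.
#' @return integer scalar.
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))

#' The vocabulary attached to an object
#' @param x an [EmbeddingMatrix] or [ProjectionModel].
#' @return a [Vocabulary].
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' Seed pairs as a data.frame
#' @param x a [SeedPairSet].
#' @return data.frame with columns professional, consumer, context.
#' @export
setGeneric("seedPairs", function(x) standardGeneric("seedPairs"))

#' Embedding dimensionality
#' @param x an [EmbeddingMatrix] or [ProjectionModel].
#' @return integer scalar.
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' Embedding training method
#' @param x an [EmbeddingMatrix].
#' @return character scalar.
#' @export
setGeneric("embeddingMethod", function(x) standardGeneric("embeddingMethod"))

#' Cosine similarity between two tokens
#'
#' Measured either in the raw pretrained space (when `x` is an
#' [EmbeddingMatrix]) or in the adapted projected space (when `x` is a
#' [ProjectionModel]).
#'
#' @param x an [EmbeddingMatrix] or [ProjectionModel].
#' @param a,b tokens.
#' @return numeric scalar in `[-1, 1]`.
#' @export
setGeneric("cosineSimilarity", function(x, a, b) standardGeneric("cosineSimilarity"))

#' The projection matrix S
#' @param x a [ProjectionModel].
#' @return numeric matrix.
#' @export
setGeneric("projectionMatrix", function(x) standardGeneric("projectionMatrix"))

#' Projected dimensionality s
#' @param x a [ProjectionModel].
#' @return integer scalar.
#' @export
setGeneric("projectionDim", function(x) standardGeneric("projectionDim"))

#' Candidate entries of a ranked list
#' @param x a [CandidateList].
#' @return data.frame with columns token, similarity.
#' @export
setGeneric("candidateEntries", function(x) standardGeneric("candidateEntries"))

#' Mean reciprocal rank value
#' @param x an [EvalResult].
#' @return numeric scalar in `[0, 1]`.
#' @export
setGeneric("mrrValue", function(x) standardGeneric("mrrValue"))

#' Per-query rank of the first relevant synonym
#' @param x an [EvalResult].
#' @return named numeric vector (Inf when nothing relevant was returned).
#' @export
setGeneric("perQueryRank", function(x) standardGeneric("perQueryRank"))
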