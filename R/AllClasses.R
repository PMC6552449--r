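#' @import methods
NULL

#' Special placeholder tokens
#'
#' Tokens used by [preprocessCorpus()]: `URL_TOKEN` replaces tokens that look
#' like URLs and `UNKNOW_TOKEN` replaces tokens whose corpus-wide frequency
#' falls below the preprocessing threshold. Both are always present in a
#' [Vocabulary] and are excluded from retrieval candidates.
#'
#' @return Named character vector with elements `url` and `unknow`.
#' @export
#' @examples
#' specialTokens()
specialTokens <- function() {
  c(url = "URL_TOKEN", unknow = "UNKNOW_TOKEN")
}

#' Corpus: an ordered collection of tokenized messages
#'
#' One message is one character vector of tokens (segmentation happens
#' upstream; any tokenizer can be plugged in before construction). Message
#' order is preserved by all operations.
#'
#' @slot messages list of character vectors, one per message.
#' @slot sourceLabel free-text provenance label.
#' @export
setClass("Corpus",
  representation(messages = "list", sourceLabel = "character"),
  prototype(messages = list(), sourceLabel = NA_character_)
)

setValidity("Corpus", function(object) {
  msgs <- object@messages
  if (!all(vapply(msgs, is.character, logical(1)))) {
    return("every message must be a character vector of tokens")
  }
  bad <- vapply(msgs, function(m) any(is.na(m) | !nzchar(m)), logical(1))
  if (any(bad)) {
    return(sprintf("message %d contains an empty or NA token", which(bad)[1]))
  }
  TRUE
})

#' Vocabulary: token index with corpus frequencies
#'
#' Maps each distinct token of a corpus to a contiguous 1-based integer id
#' and records its occurrence count. The special placeholder tokens of
#' [specialTokens()] are always members (possibly with frequency zero).
#' Tokens are ordered by descending frequency, ties broken lexicographically
#' (C locale), so ids are reproducible.
#'
#' @slot tokens ordered character vector of distinct tokens.
#' @slot freq integer vector of counts, parallel to `tokens`.
#' @export
setClass("Vocabulary",
  representation(tokens = "character", freq = "integer")
)

setValidity("Vocabulary", function(object) {
  if (length(object@tokens) != length(object@freq)) {
    return("tokens and freq must have equal length")
  }
  if (anyDuplicated(object@tokens)) return("tokens must be unique")
  if (any(object@freq < 0)) return("frequencies must be non-negative")
  sp <- specialTokens()
  if (!all(sp %in% object@tokens)) {
    return("special tokens URL_TOKEN and UNKNOW_TOKEN must be present")
  }
  TRUE
})

#' SeedPairSet: labeled professional/consumer term pairs
#'
#' The supervision unit of the whole pipeline: each row pairs a professional
#' term (e.g. an ICD-10 concept label, merged to a single token upstream)
#' with one consumer variant, optionally with free-text context. Duplicate
#' (professional, consumer) rows are not allowed.
#'
#' @slot pairs data.frame with character columns `professional`, `consumer`,
#'   `context`.
#' @slot provenance free-text description of where the pairs came from.
#' @export
setClass("SeedPairSet",
  representation(pairs = "data.frame", provenance = "character"),
  prototype(provenance = NA_character_)
)

setValidity("SeedPairSet", function(object) {
  p <- object@pairs
  need <- c("professional", "consumer", "context")
  if (!all(need %in% names(p))) {
    return("pairs must have columns professional, consumer, context")
  }
  if (nrow(p) > 0) {
    if (anyDuplicated(p[, c("professional", "consumer")])) {
      return("duplicate (professional, consumer) pair")
    }
    multi <- grepl("\\s", p$professional) | grepl("\\s", p$consumer)
    if (any(multi)) {
      return("pair members must be single tokens (merge multi-word terms upstream)")
    }
  }
  TRUE
})

#' EmbeddingMatrix: pretrained word vectors E
#'
#' The fixed embedding matrix learned unsupervised from the corpus: one row
#' per vocabulary token, `dim` columns. Rows are keyed by token via rownames
#' and the attached [Vocabulary]. The matrix is never modified by supervised
#' fine-tuning; adaptation happens in a [ProjectionModel] on top of it.
#'
#' @slot matrix numeric matrix (vocabulary size x dim) with token rownames.
#' @slot vocab the [Vocabulary] the rows correspond to.
#' @slot method one of `"word2vec_cbow"`, `"word2vec_skipgram"`, `"glove"`,
#'   `"fasttext"`, or `"external"` for loaded vector files.
#' @slot dim embedding dimensionality.
#' @export
setClass("EmbeddingMatrix",
  representation(matrix = "matrix", vocab = "Vocabulary",
                 method = "character", dim = "integer")
)

setValidity("EmbeddingMatrix", function(object) {
  m <- object@matrix
  if (nrow(m) != length(object@vocab@tokens)) {
    return("row count must equal vocabulary size")
  }
  if (ncol(m) != object@dim) return("column count must equal dim")
  if (object@dim < 2L) return("embedding dimension must be at least 2")
  if (any(!is.finite(m))) return("embedding matrix contains NaN or Inf")
  if (!identical(rownames(m), object@vocab@tokens)) {
    return("rownames must equal the vocabulary tokens, in order")
  }
  TRUE
})

#' ProjectionModel: trainable low-rank adaptation of an embedding space
#'
#' Holds the projection matrix S (s x e with s < e) that maps the fixed
#' pretrained matrix E into an adapted subspace: the projected vector of a
#' word with one-hot indicator M is P = S E M. Only S is trained; E stays
#' fixed. `kind = "loglinear"` is the degenerate baseline (projection size
#' 0): a 1 x e vector of elementwise feature weights applied to raw E rows.
#'
#' @slot S numeric matrix, s x e (or 1 x e weights for the log-linear kind).
#' @slot embedding the fixed [EmbeddingMatrix] being adapted.
#' @slot kind `"projection"` or `"loglinear"`.
#' @slot seed integer seed used at initialization.
#' @slot log data.frame of per-epoch training records (may be empty).
#' @export
setClass("ProjectionModel",
  representation(S = "matrix", embedding = "EmbeddingMatrix",
                 kind = "character", seed = "integer", log = "data.frame"),
  prototype(kind = "projection", seed = NA_integer_,
            log = data.frame())
)

setValidity("ProjectionModel", function(object) {
  e <- object@embedding@dim
  if (any(!is.finite(object@S))) return("S contains NaN or Inf")
  if (ncol(object@S) != e) return("S must have e columns")
  if (object@kind == "projection") {
    if (nrow(object@S) >= e) return("projection must reduce dimension (s < e)")
    if (nrow(object@S) < 1L) return("projection size must be at least 1")
  } else if (object@kind == "loglinear") {
    if (nrow(object@S) != 1L) return("log-linear weights must be a single row")
  } else {
    return("kind must be 'projection' or 'loglinear'")
  }
  TRUE
})

#' CandidateList: ranked counterpart candidates for one query term
#'
#' @slot query the query token.
#' @slot entries data.frame with columns `token` and `similarity`, sorted by
#'   descending similarity (ties: higher corpus frequency, then lexicographic).
#' @slot k the requested list length.
#' @export
setClass("CandidateList",
  representation(query = "character", entries = "data.frame", k = "integer")
)

setValidity("CandidateList", function(object) {
  e <- object@entries
  if (!all(c("token", "similarity") %in% names(e))) {
    return("entries must have columns token, similarity")
  }
  if (nrow(e) > object@k) return("entries longer than requested k")
  if (object@query %in% e$token) return("query must not appear among candidates")
  if (is.unsorted(-e$similarity)) return("entries must be sorted by similarity")
  TRUE
})

#' RankingState: supervision bookkeeping for projection training
#'
#' Stores, for every (query, synonym) supervision pair, the desired rank of
#' the synonym among the query's candidates, plus the candidate pool over
#' which ranks and sorted similarity values f(query) are computed. Desired
#' ranks for one query's synonyms are always 1..k without gaps.
#'
#' @slot pairs data.frame with columns `query`, `synonym`, `desired_rank`.
#' @slot pool character vector of candidate-pool tokens.
#' @export
setClass("RankingState",
  representation(pairs = "data.frame", pool = "character")
)

setValidity("RankingState", function(object) {
  p <- object@pairs
  if (!all(c("query", "synonym", "desired_rank") %in% names(p))) {
    return("pairs must have columns query, synonym, desired_rank")
  }
  ok <- vapply(split(p$desired_rank, p$query), function(r) {
    setequal(r, seq_along(r))
  }, logical(1))
  if (!all(ok)) return("desired ranks per query must be 1..k with no gaps")
  if (length(object@pool) < 2L) return("candidate pool must have at least 2 tokens")
  TRUE
})

#' EvalResult: mean reciprocal rank over a query sample
#'
#' @slot mrr mean of reciprocal first-relevant ranks (1/Inf counted as 0).
#' @slot nQueries number of queries evaluated.
#' @slot perQueryRank named numeric vector: rank of the first relevant
#'   synonym per query, `Inf` when no relevant synonym was returned.
#' @slot meta list of run details (seed, pool size, split, ...).
#' @export
setClass("EvalResult",
  representation(mrr = "numeric", nQueries = "integer",
                 perQueryRank = "numeric", meta = "list"),
  prototype(meta = list())
)

setValidity("EvalResult", function(object) {
  r <- object@perQueryRank
  if (length(r) != object@nQueries) return("one rank per query required")
  if (any(r < 1)) return("ranks must be >= 1")
  recompute <- mean(ifelse(is.finite(r), 1 / r, 0))
  if (abs(recompute - object@mrr) > 1e-12) {
    return("mrr must equal the mean of reciprocal ranks")
  }
  if (object@mrr < 0 || object@mrr > 1) return("mrr must lie in [0, 1]")
  TRUE
})
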