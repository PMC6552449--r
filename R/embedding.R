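#' @include corpus.R
NULL

.embedding_methods <- c("word2vec_cbow", "word2vec_skipgram", "glove",
                        "fasttext")

# polynomial rolling hash of a string's UTF-8 bytes, reduced modulo
# n_buckets; stays far below 2^31 so it is exact and portable
.hash_ngram <- function(s, n_buckets) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1000003
  as.integer(h %% n_buckets)
}

# character n-grams of a token with boundary markers, fastText-style
.char_ngrams <- function(token, min_n, max_n) {
  s <- paste0("<", token, ">")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  out <- character(0)
  for (k in min_n:max_n) {
    if (k > n) break
    for (i in seq_len(n - k + 1L)) {
      out <- c(out, paste(ch[i:(i + k - 1L)], collapse = ""))
    }
  }
  setdiff(out, s)  # the full token already has its own vector
}

#' Train word embeddings on a corpus
#'
#' Pretrains the fixed embedding matrix E with one of four methods: CBOW or
#' skip-gram with negative sampling, GloVe (AdaGrad on the windowed
#' co-occurrence matrix), or a fastText-style skip-gram whose word
#' representation is the average of the word vector and hashed character
#' n-gram vectors. The trainers are compact single-threaded reference
#' implementations and are exactly reproducible given `seed`.
#'
#' @param corpus a preprocessed [Corpus].
#' @param method one of `"word2vec_cbow"`, `"word2vec_skipgram"`, `"glove"`,
#'   `"fasttext"`.
#' @param dim embedding dimensionality (>= 2).
#' @param window symmetric context window size.
#' @param epochs training passes over the corpus.
#' @param negative negative samples per positive (ignored by GloVe).
#' @param learningRate initial learning rate (word2vec/fastText) or AdaGrad
#'   rate (GloVe).
#' @param seed integer seed for all trainer randomness.
#' @param vocab optional prebuilt [Vocabulary]; defaults to
#'   [buildVocabulary()] of the corpus.
#' @param minN,maxN character n-gram lengths for `"fasttext"`.
#' @param nBuckets hash bucket count for fastText n-gram vectors.
#' @return an [EmbeddingMatrix].
#' @export
trainEmbeddings <- function(corpus, method = "word2vec_skipgram", dim = 100L,
                            window = 5L, epochs = 5L, negative = 5L,
                            learningRate = NULL, seed = 1L, vocab = NULL,
                            minN = 3L, maxN = 6L, nBuckets = 5000L) {
  stopifnot(is(corpus, "Corpus"))
  method <- match.arg(method, .embedding_methods)
  if (dim < 2) stop("dim must be >= 2")
  if (length(corpus@messages) == 0) stop("empty corpus")
  max_len <- max(lengths(corpus@messages))
  if (max_len < 2 && window >= max_len) {
    stop("corpus messages are shorter than the context window")
  }
  if (is.null(vocab)) vocab <- buildVocabulary(corpus)

  ids <- lapply(corpus@messages, function(m) tokenIndex(vocab, m) - 1L)
  counts <- vocab@freq
  counts[counts == 0L] <- 1L  # placeholder tokens never sampled to zero prob

  if (method == "glove") {
    lr <- if (is.null(learningRate)) 0.05 else learningRate
    m <- cpp_train_glove(ids, length(counts), as.integer(dim),
                         as.integer(window), as.integer(epochs), lr, 10.0,
                         as.integer(seed))
  } else {
    lr <- if (is.null(learningRate)) 0.025 else learningRate
    subwords <- list()
    if (method == "fasttext") {
      subwords <- lapply(vocab@tokens, function(tok) {
        grams <- .char_ngrams(tok, minN, maxN)
        if (length(grams) == 0) return(integer(0))
        vapply(grams, .hash_ngram, integer(1), n_buckets = nBuckets,
               USE.NAMES = FALSE)
      })
    }
    m <- cpp_train_w2v(ids, counts, as.integer(dim), as.integer(window),
                       as.integer(epochs), as.integer(negative), lr,
                       as.integer(seed), method == "word2vec_cbow",
                       subwords, as.integer(nBuckets))
  }
  rownames(m) <- vocab@tokens
  new("EmbeddingMatrix", matrix = m, vocab = vocab, method = method,
      dim = as.integer(dim))
}

#' @rdname vocabulary
setMethod("vocabulary", "EmbeddingMatrix", function(x) x@vocab)

#' @rdname embeddingDim
setMethod("embeddingDim", "EmbeddingMatrix", function(x) x@dim)

#' @rdname embeddingMethod
setMethod("embeddingMethod", "EmbeddingMatrix", function(x) x@method)

#' @rdname vocabTokens
setMethod("vocabTokens", "EmbeddingMatrix", function(x) x@vocab@tokens)

#' @rdname tokenFreq
setMethod("tokenFreq", "EmbeddingMatrix", function(x, tokens = NULL) {
  tokenFreq(x@vocab, tokens)
})

#' @rdname tokenIndex
setMethod("tokenIndex", "EmbeddingMatrix", function(x, tokens) {
  tokenIndex(x@vocab, tokens)
})

#' @rdname vocabSize
setMethod("vocabSize", "EmbeddingMatrix", function(x) length(x@vocab@tokens))

#' @export
setMethod("as.matrix", "EmbeddingMatrix", function(x, ...) x@matrix)

setMethod("show", "EmbeddingMatrix", function(object) {
  cat(sprintf("EmbeddingMatrix: %d x %d (%s)\n", nrow(object@matrix),
              object@dim, object@method))
})

#' Save / load word vectors in word2vec text format
#'
#' First line `"v e"`, then one line per word: the token followed by `e`
#' floats, space-separated. Values survive a round trip to at least 6
#' significant digits.
#'
#' @param embedding an [EmbeddingMatrix].
#' @param path file path.
#' @return `saveVectors` returns `path` invisibly; `loadVectors` returns an
#'   [EmbeddingMatrix] with method `"external"` (or the method recorded in
#'   a sidecar if written by [saveProjectionModel()]).
#' @export
saveVectors <- function(embedding, path) {
  stopifnot(is(embedding, "EmbeddingMatrix"))
  m <- embedding@matrix
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(rownames(m)[i], paste(sprintf("%.8g", m[i, ]), collapse = " "))
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' @rdname saveVectors
#' @export
loadVectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop("empty vector file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || any(is.na(hdr))) {
    stop("line 1: expected header 'v e'")
  }
  v <- hdr[1]; e <- hdr[2]
  if (length(lines) - 1L != v) {
    stop(sprintf("line %d: expected %d word rows, found %d",
                 length(lines), v, length(lines) - 1L))
  }
  toks <- character(v)
  m <- matrix(0, nrow = v, ncol = e)
  for (i in seq_len(v)) {
    f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(f) != e + 1L) {
      stop(sprintf("line %d: expected token + %d values, found %d fields",
                   i + 1L, e, length(f)))
    }
    toks[i] <- f[1]
    vals <- as.numeric(f[-1])
    if (any(is.na(vals))) stop(sprintf("line %d: non-numeric value", i + 1L))
    m[i, ] <- vals
  }
  rownames(m) <- toks
  sp <- specialTokens()
  freq <- rep(0L, v)
  extra <- setdiff(sp, toks)
  if (length(extra) > 0) {
    # vector files from external trainers may lack the placeholders; append
    # zero-frequency rows with small deterministic values so the vocabulary
    # contract holds
    add <- matrix(1e-8, nrow = length(extra), ncol = e)
    rownames(add) <- extra
    m <- rbind(m, add)
    toks <- c(toks, extra)
    freq <- c(freq, rep(0L, length(extra)))
  }
  vocab <- new("Vocabulary", tokens = toks, freq = freq)
  new("EmbeddingMatrix", matrix = m, vocab = vocab, method = "external",
      dim = as.integer(e))
}

.require_tokens <- function(vocab, tokens) {
  idx <- tokenIndex(vocab, tokens)
  if (anyNA(idx)) {
    stop("out-of-vocabulary token(s): ",
         paste(tokens[is.na(idx)], collapse = ", "))
  }
  idx
}

.cosine <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("degenerate vector (zero norm)")
  sum(u * v) / (nu * nv)
}

#' @rdname cosineSimilarity
setMethod("cosineSimilarity", "EmbeddingMatrix", function(x, a, b) {
  idx <- .require_tokens(x@vocab, c(a, b))
  .cosine(x@matrix[idx[1], ], x@matrix[idx[2], ])
})

# L2-normalize the rows of a matrix; errors on zero rows unless zero_ok
.normalize_rows <- function(m, zero_ok = FALSE) {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) {
    if (!zero_ok) stop("degenerate vector (zero norm)")
    n[n == 0] <- 1
  }
  m / n
}
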