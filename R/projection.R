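#' @include embedding.R
NULL

#' Default projected dimensionality
#'
#' About one order of magnitude below the embedding size, rounded to a
#' multiple of 10 (with a floor of 5 and a ceiling of e - 1), matching the
#' regime in which the low-rank adaptation works best.
#'
#' @param e embedding dimensionality.
#' @return integer projection size.
#' @export
defaultProjectionSize <- function(e) {
  s <- 10L * as.integer(round(e / 100))
  max(5L, min(as.integer(e) - 1L, s))
}

#' Initialize a projection model
#'
#' Creates the trainable matrix S (s x e, s < e) with entries drawn i.i.d.
#' uniform on \eqn{[-a, a]}, \eqn{a = \sqrt{6 / (s + e)}} (a symmetric,
#' scale-stable range for "initialized uniformly at random"). The projected
#' vector of a word with one-hot indicator M is P = S E M; training updates
#' only S, never E.
#'
#' @param embedding the fixed [EmbeddingMatrix] E.
#' @param s projected dimensionality, `1 <= s < e`. `s = 0` selects the
#'   log-linear baseline: a single row of elementwise feature weights
#'   (initialized at 1) scoring raw-E similarities.
#' @param seed integer seed.
#' @return a [ProjectionModel].
#' @export
#' @examples
#' \dontrun{
#' m <- initProjection(emb, s = 20, seed = 1)
#' }
initProjection <- function(embedding, s = defaultProjectionSize(embeddingDim(embedding)),
                           seed = 1L) {
  stopifnot(is(embedding, "EmbeddingMatrix"))
  e <- embedding@dim
  s <- as.integer(s)
  if (s == 0L) {
    S <- matrix(1, nrow = 1L, ncol = e)
    return(new("ProjectionModel", S = S, embedding = embedding,
               kind = "loglinear", seed = as.integer(seed)))
  }
  if (s >= e) stop("projection must reduce dimension (s < e)")
  if (s < 1L) stop("projection size must be at least 1")
  a <- sqrt(6 / (s + e))
  S <- withr::with_seed(as.integer(seed), {
    matrix(stats::runif(s * e, -a, a), nrow = s, ncol = e)
  })
  new("ProjectionModel", S = S, embedding = embedding, kind = "projection",
      seed = as.integer(seed))
}

#' @rdname projectionMatrix
setMethod("projectionMatrix", "ProjectionModel", function(x) x@S)

#' @rdname projectionDim
setMethod("projectionDim", "ProjectionModel", function(x) nrow(x@S))

#' @rdname vocabulary
setMethod("vocabulary", "ProjectionModel", function(x) x@embedding@vocab)

#' @rdname embeddingDim
setMethod("embeddingDim", "ProjectionModel", function(x) x@embedding@dim)

#' @rdname vocabTokens
setMethod("vocabTokens", "ProjectionModel", function(x) x@embedding@vocab@tokens)

#' @rdname tokenFreq
setMethod("tokenFreq", "ProjectionModel", function(x, tokens = NULL) {
  tokenFreq(x@embedding@vocab, tokens)
})

setMethod("show", "ProjectionModel", function(object) {
  if (object@kind == "loglinear") {
    cat(sprintf("ProjectionModel (log-linear baseline) over %d x %d embedding\n",
                nrow(object@embedding@matrix), object@embedding@dim))
  } else {
    cat(sprintf("ProjectionModel: S %d x %d over %s embedding (%d words)\n",
                nrow(object@S), ncol(object@S), object@embedding@method,
                nrow(object@embedding@matrix)))
  }
  if (nrow(object@log) > 0) {
    last <- object@log[nrow(object@log), ]
    cat(sprintf("  trained %d epochs; last ranking loss %.1f, train MRR %.3f\n",
                nrow(object@log), last$ranking_loss, last$train_mrr))
  }
})

# adapted-space vectors for a set of row indices: rows of E S' (n x s);
# loglinear kind applies elementwise weights instead
.project_rows <- function(model, idx) {
  E <- model@embedding@matrix
  if (model@kind == "loglinear") {
    E[idx, , drop = FALSE] * rep(model@S[1, ], each = length(idx))
  } else {
    E[idx, , drop = FALSE] %*% t(model@S)
  }
}

#' Project a token into the adapted space
#'
#' Returns S E M for the one-hot indicator M of `token`: the length-s
#' adapted vector. For the log-linear baseline, returns the elementwise
#' reweighted raw vector instead.
#'
#' @param model a [ProjectionModel].
#' @param token a vocabulary token.
#' @return numeric vector of length `projectionDim(model)` (or e for the
#'   log-linear kind).
#' @export
projectToken <- function(model, token) {
  stopifnot(is(model, "ProjectionModel"))
  idx <- tokenIndex(model@embedding@vocab, token)
  if (is.na(idx)) stop("out-of-vocabulary token: ", token)
  as.vector(.project_rows(model, idx))
}

#' Project the whole vocabulary
#'
#' @param model a [ProjectionModel].
#' @return numeric matrix (vocabulary size x s) with token rownames.
#' @export
projectVocabulary <- function(model) {
  stopifnot(is(model, "ProjectionModel"))
  m <- .project_rows(model, seq_along(model@embedding@vocab@tokens))
  rownames(m) <- model@embedding@vocab@tokens
  m
}

#' @rdname cosineSimilarity
setMethod("cosineSimilarity", "ProjectionModel", function(x, a, b) {
  idx <- .require_tokens(x@embedding@vocab, c(a, b))
  p <- .project_rows(x, idx)
  .cosine(p[1, ], p[2, ])
})

#' Grow the projection while preserving what was learned
#'
#' As the seed-pair set grows over review iterations, the adapted subspace
#' can be enlarged without forgetting: the original rows of S are kept
#' bit-identical and `sNew - s` freshly uniform-initialized rows are
#' appended.
#'
#' @param model a [ProjectionModel] of kind `"projection"`.
#' @param sNew new projected dimensionality, `s < sNew < e`.
#' @param seed integer seed for the appended rows.
#' @return a [ProjectionModel] with `sNew` rows.
#' @export
expandProjection <- function(model, sNew, seed = 1L) {
  stopifnot(is(model, "ProjectionModel"))
  if (model@kind != "projection") {
    stop("the log-linear baseline has no projection to expand")
  }
  s <- nrow(model@S); e <- ncol(model@S)
  sNew <- as.integer(sNew)
  if (sNew <= s) stop("sNew must exceed the current projection size")
  if (sNew >= e) stop("projection must reduce dimension (s < e)")
  a <- sqrt(6 / (sNew + e))
  extra <- withr::with_seed(as.integer(seed), {
    matrix(stats::runif((sNew - s) * e, -a, a), nrow = sNew - s, ncol = e)
  })
  new("ProjectionModel", S = rbind(model@S, extra), embedding = model@embedding,
      kind = "projection", seed = model@seed, log = model@log)
}

#' Save / load a projection model checkpoint
#'
#' A checkpoint is a directory holding `vectors.txt` (the fixed E in
#' word2vec text format), `S.txt` (header `"s e"`, then rows of floats) and
#' `meta.json` (dims, kind, method, seed, frequencies).
#'
#' @param model a [ProjectionModel].
#' @param dir checkpoint directory (created if missing).
#' @return `saveProjectionModel` returns `dir` invisibly;
#'   `loadProjectionModel` returns the restored [ProjectionModel].
#' @export
saveProjectionModel <- function(model, dir) {
  stopifnot(is(model, "ProjectionModel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveVectors(model@embedding, file.path(dir, "vectors.txt"))
  S <- model@S
  con <- file(file.path(dir, "S.txt"), "w", encoding = "UTF-8")
  writeLines(sprintf("%d %d", nrow(S), ncol(S)), con)
  writeLines(vapply(seq_len(nrow(S)), function(i) {
    paste(sprintf("%.17g", S[i, ]), collapse = " ")
  }, character(1)), con)
  close(con)
  meta <- list(kind = model@kind, seed = model@seed,
               method = model@embedding@method,
               dim = model@embedding@dim, s = nrow(S),
               freq = as.list(stats::setNames(model@embedding@vocab@freq,
                                              model@embedding@vocab@tokens)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname saveProjectionModel
#' @export
loadProjectionModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  emb <- loadVectors(file.path(dir, "vectors.txt"))
  freq <- unlist(meta$freq)
  f <- emb@vocab@freq
  hit <- match(names(freq), emb@vocab@tokens)
  f[hit[!is.na(hit)]] <- as.integer(freq[!is.na(hit)])
  emb@vocab@freq <- f
  emb@method <- meta$method
  lines <- readLines(file.path(dir, "S.txt"), warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], "\\s+")[[1]])
  S <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  stopifnot(nrow(S) == hdr[1], ncol(S) == hdr[2])
  new("ProjectionModel", S = S, embedding = emb, kind = meta$kind,
      seed = as.integer(meta$seed))
}
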