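#' @include retrieval.R
NULL

#' Mean reciprocal rank of ranked candidate lists against gold pairs
#'
#' For each query (professional term in the gold set), finds the rank of the
#' first gold synonym appearing in its candidate list; the reciprocal rank
#' of a query whose synonyms all miss the list is 0. MRR is the mean of the
#' reciprocal ranks over all queries.
#'
#' @param gold a [SeedPairSet]; its professional terms are the queries and
#'   its consumer terms the relevant synonyms.
#' @param ranked a named list of [CandidateList] objects keyed by query, or
#'   a function `function(query)` returning one.
#' @return an [EvalResult].
#' @export
#' @examples
#' \dontrun{
#' res <- meanReciprocalRank(gold, function(q) rankCandidates(model, q, k = 50))
#' mrrValue(res)
#' }
meanReciprocalRank <- function(gold, ranked) {
  stopifnot(is(gold, "SeedPairSet"))
  if (nrow(gold@pairs) == 0) stop("empty gold pair set")
  queries <- unique(gold@pairs$professional)
  get_list <- if (is.function(ranked)) {
    ranked
  } else {
    function(q) {
      if (is.null(ranked[[q]])) stop("no candidate list for query: ", q)
      ranked[[q]]
    }
  }
  ranks <- stats::setNames(rep(Inf, length(queries)), queries)
  for (q in queries) {
    cl <- get_list(q)
    stopifnot(is(cl, "CandidateList"))
    syn <- gold@pairs$consumer[gold@pairs$professional == q]
    pos <- match(syn, cl@entries$token)
    if (any(!is.na(pos))) ranks[q] <- min(pos, na.rm = TRUE)
  }
  new("EvalResult",
      mrr = mean(ifelse(is.finite(ranks), 1 / ranks, 0)),
      nQueries = length(queries), perQueryRank = ranks, meta = list())
}

#' @rdname mrrValue
setMethod("mrrValue", "EvalResult", function(x) x@mrr)

#' @rdname perQueryRank
setMethod("perQueryRank", "EvalResult", function(x) x@perQueryRank)

setMethod("show", "EvalResult", function(object) {
  fin <- is.finite(object@perQueryRank)
  cat(sprintf("EvalResult: MRR %.4f over %d queries (mean first-relevant rank %.1f, %d misses)\n",
              object@mrr, object@nQueries,
              if (any(fin)) mean(object@perQueryRank[fin]) else NA_real_,
              sum(!fin)))
})

#' Evaluate a model on a random sample of seed pairs
#'
#' Samples `nEval` pairs without replacement (reproducibly by `seed`),
#' queries each sampled pair's professional term (or consumer term when
#' `direction = "cons2prof"`) against the evaluation candidate pool, and
#' returns the MRR. The sampled pairs are reported in `meta$evalPairs` and
#' the remainder in `meta$trainPairs` so that any training in the same run
#' can exclude the evaluation sample.
#'
#' @param seedPairs the full [SeedPairSet].
#' @param model a [ProjectionModel] or [EmbeddingMatrix].
#' @param nEval sample size (default 100, capped at the number of pairs).
#' @param seed integer seed for the sample.
#' @param pool evaluation candidate pool; default is the professional-term
#'   list plus all seed-pair members plus the 1000 most frequent tokens.
#' @param professionalTerms optional professional-term list included in the
#'   default pool.
#' @param direction `"prof2cons"` (default) or `"cons2prof"`.
#' @return an [EvalResult] with sampling details in `meta`.
#' @export
evaluateProtocol <- function(seedPairs, model, nEval = 100L, seed = 1L,
                             pool = NULL, professionalTerms = NULL,
                             direction = c("prof2cons", "cons2prof")) {
  stopifnot(is(seedPairs, "SeedPairSet"))
  direction <- match.arg(direction)
  n <- nrow(seedPairs@pairs)
  if (n == 0) stop("empty gold pair set")
  if (nEval > n) stop("nEval exceeds the number of available pairs")
  idx <- withr::with_seed(as.integer(seed), sample.int(n, nEval))
  df <- seedPairs@pairs
  eval_df <- df[sort(idx), , drop = FALSE]
  train_df <- df[setdiff(seq_len(n), idx), , drop = FALSE]
  rownames(eval_df) <- rownames(train_df) <- NULL
  if (direction == "cons2prof") {
    eval_gold <- SeedPairSet(eval_df$consumer, eval_df$professional,
                             provenance = "evaluation sample (reversed)")
  } else {
    eval_gold <- new("SeedPairSet", pairs = eval_df,
                     provenance = "evaluation sample")
  }
  vocab <- vocabulary(model)
  if (is.null(pool)) {
    pool <- buildCandidatePool(vocab, seedPairs, topN = 1000L,
                               extra = professionalTerms %||% character(0))
  }
  res <- meanReciprocalRank(eval_gold, function(q) {
    rankCandidates(model, q, k = length(pool), pool = pool)
  })
  res@meta <- list(seed = as.integer(seed), poolSize = length(pool),
                   direction = direction,
                   evalPairs = new("SeedPairSet", pairs = eval_df,
                                   provenance = "evaluation sample"),
                   trainPairs = new("SeedPairSet", pairs = train_df,
                                    provenance = "training remainder"))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Before/after fine-tuning experiment grid
#'
#' For every combination of embedding method and dimensionality: pretrain
#' embeddings, split the seed pairs concept-wise into training and held-out
#' sets, record the held-out MRR of the raw pretrained space ("before"),
#' fine-tune the projection on the training pairs, and record the held-out
#' MRR of the adapted space ("after"). When `projectionSizes` is supplied
#' the sweep additionally varies the projection size, with size 0 denoting
#' the log-linear baseline.
#'
#' @param corpus a preprocessed [Corpus].
#' @param seedPairs the supervision [SeedPairSet].
#' @param methods character vector of embedding methods.
#' @param dims integer vector of embedding sizes.
#' @param projectionSizes optional integer vector of projection sizes
#'   (0 = log-linear baseline); default is [defaultProjectionSize()] per dim.
#' @param trainFraction concept-level fraction of pairs used for training.
#' @param config a [trainConfig()].
#' @param seed integer seed governing the split and initialization.
#' @param professionalTerms optional term list added to the evaluation pool.
#' @param embedArgs named list of extra arguments to [trainEmbeddings()]
#'   (window, epochs, ...).
#' @param path optional TSV output path for the result table.
#' @return data.frame with columns method, dim, s, mrr_before, mrr_after.
#' @export
runExperimentGrid <- function(corpus, seedPairs,
                              methods = "word2vec_skipgram", dims = 100L,
                              projectionSizes = NULL, trainFraction = 0.7,
                              config = trainConfig(), seed = 1L,
                              professionalTerms = NULL,
                              embedArgs = list(), path = NULL) {
  stopifnot(is(corpus, "Corpus"), is(seedPairs, "SeedPairSet"))
  split <- splitPairs(seedPairs, trainFraction, seed = seed)
  rows <- list()
  for (method in methods) {
    for (dim in dims) {
      emb <- do.call(trainEmbeddings,
                     c(list(corpus = corpus, method = method,
                            dim = as.integer(dim), seed = as.integer(seed)),
                       embedArgs))
      pool <- buildCandidatePool(emb@vocab, seedPairs, topN = 1000L,
                                 extra = professionalTerms %||% character(0))
      before <- meanReciprocalRank(split$test, function(q) {
        rankCandidates(emb, q, k = length(pool), pool = pool)
      })
      svals <- projectionSizes %||% defaultProjectionSize(dim)
      for (s in svals) {
        model <- initProjection(emb, s = s, seed = seed)
        fitted <- fitProjection(model, split$train, config,
                                heldout = split$test)
        after <- meanReciprocalRank(split$test, function(q) {
          rankCandidates(fitted, q, k = length(pool), pool = pool)
        })
        rows[[length(rows) + 1L]] <-
          data.frame(method = method, dim = as.integer(dim),
                     s = as.integer(s), mrr_before = before@mrr,
                     mrr_after = after@mrr)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
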