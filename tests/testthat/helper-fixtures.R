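# fixtures are built in code; nothing is read from disk

# vocabulary over the given tokens (placeholders appended automatically)
toy_vocab <- function(tokens, freq = rep(5L, length(tokens))) {
  sp <- setdiff(specialTokens(), tokens)
  new("Vocabulary", tokens = c(tokens, sp),
      freq = c(as.integer(freq), rep(0L, length(sp))))
}

# embedding with explicitly chosen row vectors (rows named by token)
toy_embedding <- function(m, freq = rep(5L, nrow(m))) {
  sp <- setdiff(specialTokens(), rownames(m))
  if (length(sp) > 0) {
    pad <- matrix(1e-6, nrow = length(sp), ncol = ncol(m),
                  dimnames = list(sp, NULL))
    freq <- c(freq, rep(0L, length(sp)))
    m <- rbind(m, pad)
  }
  vocab <- new("Vocabulary", tokens = rownames(m), freq = as.integer(freq))
  new("EmbeddingMatrix", matrix = m, vocab = vocab, method = "external",
      dim = ncol(m))
}

# random embedding for property tests
random_embedding <- function(v = 10, e = 6, seed = 1) {
  withr::with_seed(seed, {
    toks <- sprintf("w%02d", seq_len(v))
    m <- matrix(stats::rnorm(v * e), v, e, dimnames = list(toks, NULL))
    toy_embedding(m, freq = sample(1:100, v, replace = TRUE))
  })
}

# a hand-rolled CandidateList (bypasses any model)
toy_candidates <- function(query, tokens, sims, k = length(tokens)) {
  ord <- order(-sims)
  new("CandidateList", query = query,
      entries = data.frame(token = tokens[ord], similarity = sims[ord]),
      k = as.integer(max(k, length(tokens))))
}

# cache of full synthetic pipeline runs shared across test files
.pipeline_cache <- new.env(parent = emptyenv())
cached_pipeline <- function(seed) {
  key <- as.character(seed)
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- runSyntheticPipeline(seed = seed)
  }
  .pipeline_cache[[key]]
}

# small-but-real trained embedding shared by embedding/retrieval tests
.small_emb_cache <- new.env(parent = emptyenv())
cached_small_embedding <- function(seed = 1) {
  key <- as.character(seed)
  if (is.null(.small_emb_cache[[key]])) {
    cfg <- generatorConfig(nConcepts = 10L, nMessages = 2000L, seed = seed)
    gen <- generateCorpus(cfg)
    emb <- trainEmbeddings(preprocessCorpus(gen$corpus, minCount = 1L),
                           method = "word2vec_skipgram", dim = 30L,
                           epochs = 5L, seed = seed)
    .small_emb_cache[[key]] <- list(gen = gen, emb = emb)
  }
  .small_emb_cache[[key]]
}
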