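test_that("MRR follows the reciprocal-rank definition exactly", {
  gold <- SeedPairSet(c("q1", "q2", "q3"), c("s1", "s2", "s3"))
  lists <- list(
    q1 = toy_candidates("q1", c("s1", "x", "y"), c(0.9, 0.8, 0.7)),
    q2 = toy_candidates("q2", c("x", "s2", "y"), c(0.9, 0.8, 0.7)),
    q3 = toy_candidates("q3", c("x", "y", "z", "s3"), c(0.9, 0.8, 0.7, 0.6))
  )
  res <- meanReciprocalRank(gold, lists)
  expect_equal(mrrValue(res), 7 / 12)  # (1 + 1/2 + 1/4) / 3
  expect_equal(unname(perQueryRank(res)), c(1, 2, 4))

  # all synonyms at rank 1
  top <- list(q1 = lists$q1,
              q2 = toy_candidates("q2", c("s2", "x"), c(0.9, 0.1)),
              q3 = toy_candidates("q3", c("s3", "x"), c(0.9, 0.1)))
  expect_equal(mrrValue(meanReciprocalRank(gold, top)), 1.0)

  # a missing synonym contributes 0
  none <- list(q1 = toy_candidates("q1", c("x", "y"), c(0.9, 0.1)))
  r0 <- meanReciprocalRank(SeedPairSet("q1", "s1"), none)
  expect_equal(mrrValue(r0), 0)
  expect_equal(unname(perQueryRank(r0)), Inf)

  expect_error(meanReciprocalRank(SeedPairSet(), lists), "empty gold")
})

test_that("MRR equals a brute-force first-hit scan on random instances", {
  withr::with_seed(99, {
    for (i in 1:10) {
      n_q <- sample(3:10, 1)
      pool <- sprintf("c%02d", 1:30)
      gold_df <- data.frame(professional = sprintf("q%02d", seq_len(n_q)),
                            consumer = sample(pool, n_q, replace = TRUE))
      gold_df <- unique(gold_df)
      gold <- SeedPairSet(gold_df$professional, gold_df$consumer)
      lists <- lapply(unique(gold_df$professional), function(q) {
        shown <- sample(pool, sample(5:30, 1))
        toy_candidates(q, shown, seq(0.99, 0.01, length.out = length(shown)))
      })
      names(lists) <- unique(gold_df$professional)
      # independent brute-force scan
      rr <- vapply(unique(gold_df$professional), function(q) {
        syn <- gold_df$consumer[gold_df$professional == q]
        toks <- candidateEntries(lists[[q]])$token
        hit <- Inf
        for (r in seq_along(toks)) {
          if (toks[r] %in% syn) { hit <- r; break }
        }
        if (is.finite(hit)) 1 / hit else 0
      }, numeric(1))
      expect_equal(mrrValue(meanReciprocalRank(gold, lists)), mean(rr))
    }
  })
})

test_that("MRR is monotone when a gold synonym moves up the list", {
  gold <- SeedPairSet("q1", "s1")
  low <- list(q1 = toy_candidates("q1", c("a", "b", "s1"), c(0.9, 0.8, 0.7)))
  high <- list(q1 = toy_candidates("q1", c("a", "s1", "b"), c(0.9, 0.8, 0.7)))
  expect_gt(mrrValue(meanReciprocalRank(gold, high)),
            mrrValue(meanReciprocalRank(gold, low)))
})

test_that("random rankings concentrate near the closed-form expected MRR", {
  # single-synonym queries, uniform random permutation of a pool of size P:
  # E[1/rank] = sum_r (1/r) / P
  P <- 20L
  pool <- sprintf("c%02d", seq_len(P))
  expected <- sum(1 / seq_len(P)) / P
  withr::with_seed(123, {
    rr <- replicate(3000, {
      1 / match("c01", sample(pool))
    })
  })
  expect_equal(mean(rr), expected, tolerance = 0.05)
  # and the package's accounting agrees on a small batch of them
  withr::with_seed(124, {
    gold <- SeedPairSet(sprintf("q%03d", 1:200), rep("c01", 200))
    lists <- lapply(sprintf("q%03d", 1:200), function(q) {
      toy_candidates(q, sample(pool), seq(0.99, 0.01, length.out = P))
    })
    names(lists) <- sprintf("q%03d", 1:200)
  })
  got <- mrrValue(meanReciprocalRank(gold, lists))
  expect_equal(got, expected, tolerance = 0.2 * expected + 0.05)
})

test_that("the evaluation protocol samples reproducibly and disjointly", {
  fx <- cached_small_embedding(1)
  pairs <- fx$gen$pairs
  n <- length(pairs)
  r1 <- evaluateProtocol(pairs, fx$emb, nEval = 8L, seed = 5L)
  r2 <- evaluateProtocol(pairs, fx$emb, nEval = 8L, seed = 5L)
  expect_identical(perQueryRank(r1), perQueryRank(r2))
  expect_identical(mrrValue(r1), mrrValue(r2))

  ev <- seedPairs(r1@meta$evalPairs)
  tr <- seedPairs(r1@meta$trainPairs)
  expect_equal(nrow(ev), 8L)
  expect_equal(nrow(ev) + nrow(tr), n)
  key <- function(d) paste(d$professional, d$consumer)
  expect_length(intersect(key(ev), key(tr)), 0)

  all_eval <- evaluateProtocol(pairs, fx$emb, nEval = n, seed = 1L)
  expect_equal(all_eval@nQueries,
               length(unique(seedPairs(pairs)$professional)))
  expect_error(evaluateProtocol(pairs, fx$emb, nEval = n + 1L),
               "exceeds")
})

test_that("the experiment grid reports before/after MRR per cell", {
  fx <- cached_small_embedding(1)
  corpus <- preprocessCorpus(fx$gen$corpus, minCount = 1L)
  out <- runExperimentGrid(corpus, fx$gen$pairs,
                           methods = "word2vec_skipgram", dims = 20L,
                           projectionSizes = c(0L, 8L),
                           config = trainConfig(epochs = 10L, seed = 1),
                           seed = 1L, embedArgs = list(epochs = 3L))
  expect_equal(nrow(out), 2L)
  expect_equal(names(out), c("method", "dim", "s", "mrr_before", "mrr_after"))
  expect_equal(out$method, rep("word2vec_skipgram", 2))
  expect_equal(out$dim, rep(20L, 2))
  expect_equal(out$s, c(0L, 8L))
  expect_true(all(out$mrr_before >= 0 & out$mrr_before <= 1))
  expect_true(all(out$mrr_after >= 0 & out$mrr_after <= 1))
  # the log-linear baseline row really used the degenerate projection
  f <- withr::local_tempfile(fileext = ".tsv")
  out2 <- runExperimentGrid(corpus, fx$gen$pairs,
                            methods = "word2vec_skipgram", dims = 20L,
                            projectionSizes = 0L,
                            config = trainConfig(epochs = 5L, seed = 1),
                            seed = 1L, embedArgs = list(epochs = 3L),
                            path = f)
  expect_true(file.exists(f))
  tsv <- utils::read.delim(f)
  expect_equal(tsv$s, 0L)
})
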