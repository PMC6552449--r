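# hand-set geometry: query q on the x-axis, candidates at fixed cosines
handset_model <- function(sims = c(c1 = 0.9, c2 = 0.5, c3 = 0.1),
                          freq = c(q = 50L, c1 = 30L, c2 = 20L, c3 = 10L)) {
  ang <- acos(sims)
  m <- rbind(q = c(1, 0, 0),
             c1 = c(cos(ang[1]), sin(ang[1]), 0),
             c2 = c(cos(ang[2]), sin(ang[2]), 0),
             c3 = c(cos(ang[3]), sin(ang[3]), 0))
  emb <- toy_embedding(m, freq = unname(freq[rownames(m)]))
  model <- initProjection(emb, s = 2, seed = 1)
  model@S <- cbind(diag(2), c(0, 0))  # first two coordinates: cosines intact
  model
}

test_that("desired ranks order synonyms by frequency then lexicographically", {
  v <- toy_vocab(c("flu", "grippe", "influenza", "cold"),
                 freq = c(1000L, 900L, 500L, 100L))
  one <- assignDesiredRanks(SeedPairSet("flu", "grippe"), v,
                            bidirectional = FALSE)
  expect_equal(one@pairs$desired_rank, 1L)

  sp <- SeedPairSet(c("flu", "flu"), c("influenza", "grippe"))
  st <- assignDesiredRanks(sp, v, bidirectional = FALSE)
  got <- st@pairs[order(st@pairs$desired_rank), ]
  expect_equal(got$synonym, c("grippe", "influenza"))  # 900 beats 500

  # random seed sets: ranks per query are a permutation of 1..k
  withr::with_seed(23, {
    for (i in 1:10) {
      toks <- sprintf("t%02d", 1:12)
      vv <- toy_vocab(toks, freq = sample(1:999, 12))
      qs <- sample(toks[1:4], 6, replace = TRUE)
      syns <- sample(toks[5:12], 6)
      df <- unique(data.frame(q = qs, s = syns))
      spp <- SeedPairSet(df$q, df$s)
      stt <- assignDesiredRanks(spp, vv)
      for (ranks in split(stt@pairs$desired_rank, stt@pairs$query)) {
        expect_setequal(ranks, seq_along(ranks))
      }
    }
  })

  expect_error(assignDesiredRanks(SeedPairSet("flu", "nope"), v), "nope")
})

test_that("ranking loss counts rank displacement and is zero at the optimum", {
  model <- handset_model()
  v <- vocabulary(model)
  # c1 is the most similar candidate: desired rank 1, current rank 1 -> 0
  st1 <- assignDesiredRanks(SeedPairSet("q", "c1"), v, pool = c("c1", "c2", "c3"),
                            bidirectional = FALSE)
  expect_equal(rankingLoss(model, st1), 0)

  # c3 currently ranks 3rd among candidates but is wanted 1st -> |3 - 1| = 2
  st3 <- assignDesiredRanks(SeedPairSet("q", "c3"), v, pool = c("c1", "c2", "c3"),
                            bidirectional = FALSE)
  expect_equal(rankingLoss(model, st3), 2)
  expect_equal(rankingLoss(model, st3, variant = "squared"), 4)

  expect_error(assignDesiredRanks(SeedPairSet(), v), "no supervision")
})

test_that("ranking loss equals a brute-force loop over all pairs", {
  emb <- random_embedding(v = 15, e = 6, seed = 42)
  toks <- setdiff(vocabTokens(emb), specialTokens())
  withr::with_seed(42, {
    df <- unique(data.frame(q = sample(toks[1:5], 8, replace = TRUE),
                            s = sample(toks[6:15], 8)))
  })
  sp <- SeedPairSet(df$q, df$s)
  model <- initProjection(emb, s = 3, seed = 2)
  pool <- toks
  st <- assignDesiredRanks(sp, vocabulary(emb), pool = pool)

  brute <- 0
  for (i in seq_len(nrow(st@pairs))) {
    q <- st@pairs$query[i]
    f <- sortedSimilarities(model, st, q)
    brute <- brute + abs(match(st@pairs$synonym[i], names(f)) -
                           st@pairs$desired_rank[i])
  }
  expect_equal(rankingLoss(model, st), brute)
})

test_that("surrogate loss equals the squared gap to the desired-rank similarity", {
  model <- handset_model()
  st <- assignDesiredRanks(SeedPairSet("q", "c2"), vocabulary(model),
                           pool = c("c1", "c2", "c3"), bidirectional = FALSE)
  # f(q) = (0.9, 0.5, 0.1); desired rank 1 -> target 0.9, own sim 0.5
  expect_equal(surrogateLoss(model, st, "q", "c2"), (0.9 - 0.5)^2,
               tolerance = 1e-12)

  # synonym already at its desired position -> zero loss
  st1 <- assignDesiredRanks(SeedPairSet("q", "c1"), vocabulary(model),
                            pool = c("c1", "c2", "c3"), bidirectional = FALSE)
  expect_equal(surrogateLoss(model, st1, "q", "c1"), 0, tolerance = 1e-12)

  # desired rank beyond the pool is an error
  tiny <- assignDesiredRanks(SeedPairSet(c("q", "q"), c("c1", "c2")),
                             vocabulary(model), pool = c("q", "c1"),
                             bidirectional = FALSE)
  low <- tiny@pairs$synonym[tiny@pairs$desired_rank == 2L]
  expect_error(surrogateLoss(model, tiny, "q", low), "pool too small")
})

test_that("the analytic gradient matches central finite differences", {
  worst <- 0
  checked <- 0
  rep <- 0
  while (checked < 20 && rep < 100) {
    rep <- rep + 1
    emb <- random_embedding(v = 10, e = 6, seed = 200 + rep)
    toks <- setdiff(vocabTokens(emb), specialTokens())
    sp <- SeedPairSet(c(toks[1], toks[1]), c(toks[3], toks[4]))
    model <- initProjection(emb, s = 3, seed = rep)
    st <- assignDesiredRanks(sp, vocabulary(emb), pool = toks)
    syn <- if (rep %% 2 == 0) toks[3] else toks[4]
    f <- sortedSimilarities(model, st, toks[1])
    k <- st@pairs$desired_rank[st@pairs$query == toks[1] &
                                 st@pairs$synonym == syn]
    tgt <- unname(f[k])
    g <- surrogateGradient(model, st, toks[1], syn, target = tgt)
    if (g$loss < 1e-8) next  # zero-loss stationary point: nothing to compare
    checked <- checked + 1
    h <- 1e-6
    num <- matrix(0, 3, 6)
    for (i in 1:3) {
      for (j in 1:6) {
        mp <- model; mp@S[i, j] <- mp@S[i, j] + h
        mm <- model; mm@S[i, j] <- mm@S[i, j] - h
        num[i, j] <- (surrogateLoss(mp, st, toks[1], syn, target = tgt) -
                        surrogateLoss(mm, st, toks[1], syn, target = tgt)) /
          (2 * h)
      }
    }
    worst <- max(worst, max(abs(num - g$grad)) / max(abs(num)))
  }
  expect_equal(checked, 20)
  expect_lt(worst, 1e-4)
})

test_that("fitting respects the fixed-E contract and is deterministic", {
  emb <- random_embedding(v = 20, e = 8, seed = 77)
  toks <- setdiff(vocabTokens(emb), specialTokens())
  sp <- SeedPairSet(toks[1:4], toks[5:8])
  model <- initProjection(emb, s = 4, seed = 1)

  noop <- fitProjection(model, sp, trainConfig(epochs = 0L))
  expect_identical(projectionMatrix(noop), projectionMatrix(model))

  cfg <- trainConfig(epochs = 5L, learningRate = 0.02, seed = 11)
  f1 <- fitProjection(model, sp, cfg)
  f2 <- fitProjection(model, sp, cfg)
  expect_identical(projectionMatrix(f1), projectionMatrix(f2))
  expect_false(identical(projectionMatrix(f1), projectionMatrix(model)))
  # E is bit-identical after training
  expect_identical(as.matrix(f1@embedding), as.matrix(emb))
  # per-epoch log with the promised fields
  expect_equal(nrow(f1@log), 5L)
  expect_named(f1@log, c("epoch", "surrogate_loss", "ranking_loss",
                         "train_mrr", "heldout_mrr"))
  expect_error(fitProjection(model, SeedPairSet(), cfg), "no supervision")
})

test_that("the review iteration merges pairs and refits", {
  emb <- random_embedding(v = 20, e = 8, seed = 78)
  toks <- setdiff(vocabTokens(emb), specialTokens())
  sp <- SeedPairSet(toks[1:3], toks[4:6])
  extra <- SeedPairSet(c(toks[1], toks[7]), c(toks[8], toks[9]))
  model <- initProjection(emb, s = 4, seed = 1)
  cfg <- trainConfig(epochs = 3L, learningRate = 0.02, seed = 5)

  res <- iterateWithReview(model, sp, extra, cfg)
  expect_equal(length(res$pairs), length(sp) + 2L)

  # an already-known accepted pair does not inflate the union
  dupes <- SeedPairSet(toks[1], toks[4])
  res2 <- iterateWithReview(model, sp, dupes, cfg)
  expect_equal(length(res2$pairs), length(sp))

  # empty accepted set reduces to a plain refit on the original seeds
  none <- new("SeedPairSet", pairs = seedPairs(SeedPairSet()),
              provenance = "empty")
  res3 <- iterateWithReview(model, sp, none, cfg)
  plain <- fitProjection(model, sp, cfg)
  expect_identical(projectionMatrix(res3$model), projectionMatrix(plain))

  # growing the projection preserves the original rows
  res4 <- iterateWithReview(model, sp, extra, cfg, expandTo = 6L)
  expect_equal(projectionDim(res4$model), 6L)
})

test_that("training logs can be written as JSON lines", {
  emb <- random_embedding(v = 12, e = 6, seed = 79)
  toks <- setdiff(vocabTokens(emb), specialTokens())
  model <- fitProjection(initProjection(emb, s = 3, seed = 1),
                         SeedPairSet(toks[1:2], toks[3:4]),
                         trainConfig(epochs = 2L, seed = 1))
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeTrainingLog(model, f)
  lines <- readLines(f)
  expect_equal(length(lines), 2L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$epoch, 1L)
  expect_true(all(c("surrogate_loss", "ranking_loss", "train_mrr") %in%
                    names(rec)))
})
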