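test_that("initialization is reproducible, bounded, and respects s < e", {
  emb <- random_embedding(v = 8, e = 10, seed = 4)
  a <- initProjection(emb, s = 4, seed = 7)
  b <- initProjection(emb, s = 4, seed = 7)
  expect_identical(projectionMatrix(a), projectionMatrix(b))
  expect_false(identical(projectionMatrix(a),
                         projectionMatrix(initProjection(emb, 4, seed = 8))))

  expect_s4_class(initProjection(emb, s = 9, seed = 1), "ProjectionModel")
  expect_error(initProjection(emb, s = 10, seed = 1), "reduce dimension")
  expect_error(initProjection(emb, s = 12, seed = 1), "reduce dimension")

  # Monte-Carlo: uniform on [-a, a] has mean 0 and sd a/sqrt(3)
  big <- random_embedding(v = 4, e = 200, seed = 1)
  S <- projectionMatrix(initProjection(big, s = 50, seed = 2))
  n <- length(S)
  bound <- sqrt(6 / (50 + 200))
  expect_true(all(abs(S) <= bound))
  se <- (bound / sqrt(3)) / sqrt(n)
  expect_lt(abs(mean(S)), 3 * se)
})

test_that("projection equals the dense matrix product with the one-hot form", {
  # selection matrix returns the first s coordinates
  emb <- random_embedding(v = 6, e = 5, seed = 9)
  model <- initProjection(emb, s = 3, seed = 1)
  model@S <- cbind(diag(3), matrix(0, 3, 2))
  tok <- vocabTokens(emb)[2]
  expect_equal(projectToken(model, tok), as.matrix(emb)[tok, 1:3])

  # random S and E match an independent product, to 1e-10
  withr::with_seed(21, {
    for (i in 1:10) {
      e <- sample(4:9, 1); s <- sample(seq_len(e - 1), 1)
      emb2 <- random_embedding(v = 7, e = e, seed = i + 100)
      m2 <- initProjection(emb2, s = s, seed = i)
      tok2 <- sample(vocabTokens(emb2), 1)
      onehot <- as.numeric(vocabTokens(emb2) == tok2)
      ref <- drop(m2@S %*% t(as.matrix(emb2)) %*% onehot)
      expect_equal(projectToken(m2, tok2), ref, tolerance = 1e-10)
    }
  })

  expect_error(projectToken(model, "missing"), "out-of-vocabulary")
})

test_that("batch projection agrees with token-wise projection", {
  emb <- random_embedding(v = 9, e = 6, seed = 2)
  model <- initProjection(emb, s = 4, seed = 3)
  P <- projectVocabulary(model)
  expect_equal(dim(P), c(vocabSize(emb), 4L))
  for (tok in vocabTokens(emb)) {
    expect_equal(P[tok, ], projectToken(model, tok))
  }
})

test_that("expanding the projection preserves the learned rows bit-exactly", {
  emb <- random_embedding(v = 6, e = 30, seed = 5)
  model <- initProjection(emb, s = 10, seed = 6)
  grown <- expandProjection(model, sNew = 20, seed = 60)
  expect_identical(projectionMatrix(grown)[1:10, ], projectionMatrix(model))
  expect_equal(projectionDim(grown), 20L)
  # projecting a word keeps its first 10 coordinates unchanged
  tok <- vocabTokens(emb)[1]
  expect_identical(projectToken(grown, tok)[1:10], projectToken(model, tok))
  # reproducible appended rows
  grown2 <- expandProjection(model, sNew = 20, seed = 60)
  expect_identical(projectionMatrix(grown), projectionMatrix(grown2))
  expect_error(expandProjection(model, sNew = 10), "exceed")
  expect_error(expandProjection(model, sNew = 30), "reduce dimension")
})

test_that("an orthonormal projection of an in-subspace embedding preserves ranking", {
  # E rows lie in the span of s orthonormal rows Q; with S = Q, projected
  # cosine ordering must equal raw-space ordering
  withr::with_seed(17, {
    e <- 8; s <- 3; v <- 12
    Q <- qr.Q(qr(matrix(stats::rnorm(e * s), e, s)))  # e x s orthonormal cols
    coords <- matrix(stats::rnorm(v * s), v, s)
    E <- coords %*% t(Q)
    rownames(E) <- sprintf("w%02d", seq_len(v))
    emb <- toy_embedding(E)
    model <- initProjection(emb, s = s, seed = 1)
    model@S <- t(Q)
    pool <- sprintf("w%02d", 2:12)
    raw <- candidateEntries(rankCandidates(emb, "w01", k = 11, pool = pool))
    proj <- candidateEntries(rankCandidates(model, "w01", k = 11, pool = pool))
    expect_equal(proj$token, raw$token)
    expect_equal(proj$similarity, raw$similarity, tolerance = 1e-10)
  })
})

test_that("training moves the projected vectors of unlabeled words too", {
  emb <- random_embedding(v = 20, e = 8, seed = 31)
  toks <- vocabTokens(emb)
  sp <- SeedPairSet(toks[1:3], toks[4:6])
  model <- initProjection(emb, s = 4, seed = 1)
  fitted <- fitProjection(model, sp,
                          trainConfig(epochs = 3L, learningRate = 0.05,
                                      seed = 1))
  unlabeled <- setdiff(toks, c(toks[1:6], specialTokens()))
  for (tok in unlabeled) {
    expect_false(identical(projectToken(model, tok),
                           projectToken(fitted, tok)))
  }
})

test_that("checkpoints restore the model faithfully", {
  emb <- random_embedding(v = 7, e = 6, seed = 8)
  model <- initProjection(emb, s = 3, seed = 2)
  dir <- withr::local_tempdir()
  saveProjectionModel(model, dir)
  back <- loadProjectionModel(dir)
  expect_equal(projectionMatrix(back), projectionMatrix(model))
  expect_equal(as.matrix(back@embedding), as.matrix(emb), tolerance = 1e-6)
  expect_equal(tokenFreq(back), tokenFreq(emb))
  expect_equal(back@kind, "projection")
})
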