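test_that("preprocessing masks URLs and rare tokens with a strict threshold", {
  co <- Corpus(list(c("http://a.b", "headache")))
  expect_equal(messages(preprocessCorpus(co, minCount = 1L))[[1]],
               c("URL_TOKEN", "headache"))

  # token at count 29 is masked, token at count 30 survives (strictly less)
  msgs <- c(rep(list(c("x", "y")), 29), rep(list(c("y", "filler")), 1))
  co <- Corpus(msgs)  # x: 29, y: 30, filler: 1
  out <- preprocessCorpus(co, minCount = 30L)
  toks <- unlist(messages(out))
  expect_false("x" %in% toks)
  expect_equal(sum(toks == "y"), 30)
  expect_equal(sum(toks == "UNKNOW_TOKEN"), 29 + 1)

  expect_error(preprocessCorpus(Corpus(list())), "empty corpus")
})

test_that("replacement count matches a brute-force recount", {
  withr::with_seed(7, {
    msgs <- replicate(30, sample(letters[1:8], sample(3:9, 1), replace = TRUE),
                      simplify = FALSE)
  })
  co <- Corpus(msgs)
  min_count <- 6L
  counts <- table(unlist(msgs))
  expected_masked <- sum(counts[counts < min_count])
  out <- preprocessCorpus(co, minCount = min_count)
  expect_equal(sum(unlist(messages(out)) == "UNKNOW_TOKEN"), expected_masked)
})

test_that("preprocessing is idempotent and conserves message shape", {
  withr::with_seed(3, {
    msgs <- replicate(20, sample(c(letters[1:6], "www.x.y"), 8, replace = TRUE),
                      simplify = FALSE)
  })
  co <- Corpus(msgs)
  once <- preprocessCorpus(co, minCount = 5L)
  twice <- preprocessCorpus(once, minCount = 5L)
  expect_identical(messages(once), messages(twice))
  expect_equal(lengths(messages(once)), lengths(messages(co)))
  expect_equal(length(once), length(co))
})

test_that("vocabulary has exact frequencies, special tokens, and full mass", {
  co <- Corpus(list(c("a", "b", "a")))
  v <- buildVocabulary(co)
  expect_setequal(vocabTokens(v), c("a", "b", specialTokens()))
  expect_equal(unname(tokenFreq(v, c("a", "b"))), c(2L, 1L))

  # frequencies equal an independent single-pass count and sum to total
  withr::with_seed(11, {
    msgs <- replicate(25, sample(letters[1:10], 12, replace = TRUE),
                      simplify = FALSE)
  })
  v2 <- buildVocabulary(Corpus(msgs))
  ref <- table(unlist(msgs))
  for (tok in names(ref)) {
    expect_equal(unname(tokenFreq(v2, tok)), as.integer(ref[[tok]]))
  }
  expect_equal(sum(tokenFreq(v2)), length(unlist(msgs)))
  # ids are a bijection onto 1..v
  expect_equal(sort(tokenIndex(v2, vocabTokens(v2))), seq_len(vocabSize(v2)))
})

test_that("professional-term selection is strict and ordered", {
  v <- toy_vocab(c("flu", "gout", "rare", "acne"),
                 freq = c(1000L, 1500L, 3L, 1500L))
  expect_equal(selectProfessionalTerms(v, c("flu", "gout"), minFreq = 1000L),
               "gout")  # 1000 is not "over 1000"
  expect_equal(selectProfessionalTerms(v, c("absent", "gout"), 10L), "gout")
  expect_equal(selectProfessionalTerms(v, character(0), 10L), character(0))
  # ties broken lexicographically after frequency
  expect_equal(selectProfessionalTerms(v, c("gout", "acne", "flu"), 500L),
               c("acne", "gout", "flu"))

  # brute-force oracle on a random instance
  withr::with_seed(5, {
    toks <- sprintf("t%02d", 1:15)
    freq <- sample(0:2000, 15, replace = TRUE)
    vv <- toy_vocab(toks, freq)
    terms <- sample(c(toks, "zz1", "zz2"), 10)
    got <- selectProfessionalTerms(vv, terms, minFreq = 800L)
    keep <- terms[terms %in% toks & tokenFreq(vv, terms) > 800]
    ref <- keep[order(-tokenFreq(vv, keep), keep, method = "radix")]
    expect_equal(got, ref)
  })
})

test_that("term merging rewrites multi-word concepts as single tokens", {
  co <- Corpus(list(c("chronic", "kidney", "disease", "hurts"),
                    c("kidney", "disease")))
  res <- mergeTerms(co, c("chronic kidney disease", "kidney disease"))
  expect_equal(messages(res$corpus)[[1]],
               c("chronic_kidney_disease", "hurts"))
  expect_equal(messages(res$corpus)[[2]], "kidney_disease")
  expect_equal(unname(res$merged["kidney disease"]), "kidney_disease")
})

test_that("seed pairs survive a write/read round trip and bad input errors", {
  sp <- SeedPairSet(c("diarrhea", "acne"), c("loose_bowels", "zits"),
                    context = c("forum", NA))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSeedPairs(sp, f)
  back <- readSeedPairs(f)
  expect_equal(seedPairs(back)$professional, seedPairs(sp)$professional)
  expect_equal(seedPairs(back)$consumer, seedPairs(sp)$consumer)
  # second write of the re-read set is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeSeedPairs(back, f2)
  expect_identical(readLines(f), readLines(f2))

  writeLines(c("professional\tconsumer\tcontext",
               "a\tb\t", "a\tb\t"), f)
  expect_warning(dup <- readSeedPairs(f), "duplicate")
  expect_equal(length(dup), 1L)

  writeLines(c("professional\tconsumer\tcontext", "a\tb\t", "only-one-field"),
             f)
  expect_error(readSeedPairs(f), "line 3")
})

test_that("term lists and corpora round-trip through their file formats", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeTermList(c("P001", "P002"), f)
  expect_equal(readTermList(f), c("P001", "P002"))

  co <- Corpus(list(c("a", "b"), c("c", "d", "e")))
  g <- withr::local_tempfile(fileext = ".txt")
  writeCorpus(co, g)
  expect_identical(messages(readCorpus(g)), messages(co))
})
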