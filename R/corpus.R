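#' @include AllGenerics.R
NULL

#' Construct a Corpus from tokenized messages
#'
#' @param messages list of character vectors (one per message) or a single
#'   character vector of whitespace-separated messages, which is then split.
#' @param sourceLabel free-text provenance label.
#' @return a [Corpus].
#' @export
#' @examples
#' Corpus(list(c("headache", "pill"), c("fever", "rest")))
Corpus <- function(messages, sourceLabel = NA_character_) {
  if (is.character(messages)) {
    messages <- strsplit(trimws(messages), "\\s+")
  }
  messages <- lapply(messages, as.character)
  new("Corpus", messages = messages, sourceLabel = sourceLabel)
}

#' @rdname messages
setMethod("messages", "Corpus", function(x) x@messages)

#' @rdname sourceLabel
setMethod("sourceLabel", "Corpus", function(x) x@sourceLabel)

#' @export
setMethod("length", "Corpus", function(x) length(x@messages))

setMethod("show", "Corpus", function(object) {
  n <- length(object@messages)
  tot <- sum(lengths(object@messages))
  cat(sprintf("Corpus: %d messages, %d tokens (source: %s)\n",
              n, tot, object@sourceLabel))
  if (n > 0) {
    hd <- object@messages[[1]]
    cat("  first message:", paste(utils::head(hd, 8), collapse = " "),
        if (length(hd) > 8) "..." else "", "\n")
  }
})

#' Read / write a corpus file
#'
#' Plain UTF-8 text, one message per line, tokens separated by whitespace.
#'
#' @param path file path.
#' @param sourceLabel provenance label attached to the corpus.
#' @return `readCorpus` returns a [Corpus]; `writeCorpus` returns `path`
#'   invisibly.
#' @export
readCorpus <- function(path, sourceLabel = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  Corpus(lines, sourceLabel = sourceLabel)
}

#' @rdname readCorpus
#' @param corpus a [Corpus].
#' @export
writeCorpus <- function(corpus, path) {
  stopifnot(is(corpus, "Corpus"))
  writeLines(vapply(corpus@messages, paste, character(1), collapse = " "),
             path, useBytes = TRUE)
  invisible(path)
}

.url_pattern <- "^(https?://|ftp://|www\\.)"

.token_counts <- function(messages) {
  tab <- table(unlist(messages, use.names = FALSE))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' Preprocess a corpus: URL masking and rare-token replacement
#'
#' Tokens that look like URLs (scheme:// or www. prefixes) are replaced by
#' `URL_TOKEN`. Any remaining token whose corpus-wide count is strictly below
#' `minCount` is replaced by `UNKNOW_TOKEN` (default threshold 30, i.e.
#' tokens occurring less than 30 times are masked). Message count and
#' per-message token counts are preserved, and the operation is idempotent.
#'
#' @param corpus a [Corpus].
#' @param minCount integer >= 1; tokens with count < minCount are masked.
#' @param urlPattern regular expression identifying URL tokens.
#' @return the preprocessed [Corpus].
#' @export
#' @examples
#' co <- Corpus(list(c("http://a.b", "headache")))
#' messages(preprocessCorpus(co, minCount = 1))[[1]]
preprocessCorpus <- function(corpus, minCount = 30L, urlPattern = .url_pattern) {
  stopifnot(is(corpus, "Corpus"))
  if (length(corpus@messages) == 0) stop("empty corpus")
  if (minCount < 1) stop("minCount must be >= 1")
  sp <- specialTokens()

  msgs <- lapply(corpus@messages, function(m) {
    m[grepl(urlPattern, m)] <- sp[["url"]]
    m
  })
  counts <- .token_counts(msgs)
  rare <- names(counts)[counts < minCount]
  rare <- setdiff(rare, sp)  # placeholders are never masked again
  if (length(rare) > 0) {
    msgs <- lapply(msgs, function(m) {
      m[m %in% rare] <- sp[["unknow"]]
      m
    })
  }
  new("Corpus", messages = msgs, sourceLabel = corpus@sourceLabel)
}

#' Build a Vocabulary from a corpus
#'
#' Tokens are ordered by descending corpus frequency, ties broken
#' lexicographically (C locale), so ids are reproducible across platforms.
#' The placeholder tokens `URL_TOKEN` and `UNKNOW_TOKEN` are always included,
#' with frequency zero when absent from the corpus.
#'
#' @param corpus a [Corpus].
#' @return a [Vocabulary].
#' @export
buildVocabulary <- function(corpus) {
  stopifnot(is(corpus, "Corpus"))
  if (length(corpus@messages) == 0) stop("empty corpus")
  counts <- .token_counts(corpus@messages)
  sp <- specialTokens()
  missing_sp <- setdiff(sp, names(counts))
  if (length(missing_sp) > 0) {
    add <- rep(0L, length(missing_sp))
    names(add) <- missing_sp
    counts <- c(counts, add)
  }
  ord <- order(-counts, names(counts), method = "radix")
  new("Vocabulary", tokens = names(counts)[ord],
      freq = as.integer(counts[ord]))
}

#' @rdname vocabTokens
setMethod("vocabTokens", "Vocabulary", function(x) x@tokens)

#' @rdname vocabSize
setMethod("vocabSize", "Vocabulary", function(x) length(x@tokens))

#' @rdname tokenIndex
setMethod("tokenIndex", "Vocabulary", function(x, tokens) {
  match(tokens, x@tokens)
})

#' @rdname tokenFreq
setMethod("tokenFreq", "Vocabulary", function(x, tokens = NULL) {
  all_freq <- stats::setNames(x@freq, x@tokens)
  if (is.null(tokens)) return(all_freq)
  out <- all_freq[tokens]
  out[is.na(out)] <- 0L
  names(out) <- tokens
  out
})

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: %d tokens, %d total occurrences\n",
              length(object@tokens), sum(object@freq)))
  k <- min(5L, length(object@tokens))
  cat("  most frequent:",
      paste(sprintf("%s(%d)", object@tokens[seq_len(k)],
                    object@freq[seq_len(k)]), collapse = " "), "\n")
})

#' Merge multi-token terms into single underscore-joined tokens
#'
#' Professional concept labels are often multi-word; downstream code treats
#' every term as a single vocabulary token, so this pre-pass rewrites each
#' occurrence of a multi-token term (exact consecutive token match) in the
#' corpus as one token joined with underscores. Longer terms are matched
#' first so nested terms resolve deterministically.
#'
#' @param corpus a [Corpus].
#' @param terms character vector of terms; multi-word terms contain spaces.
#' @return list with the rewritten `corpus` and the mapping `merged`
#'   (named character: original term -> merged token).
#' @export
mergeTerms <- function(corpus, terms) {
  stopifnot(is(corpus, "Corpus"))
  parts <- strsplit(terms, "\\s+")
  merged <- vapply(parts, paste, character(1), collapse = "_")
  names(merged) <- terms
  multi <- parts[lengths(parts) > 1]
  multi <- multi[order(-lengths(multi))]
  if (length(multi) > 0) {
    msgs <- lapply(corpus@messages, function(m) {
      for (p in multi) {
        np <- length(p)
        if (length(m) < np) next
        i <- 1L
        out <- character(0)
        while (i <= length(m)) {
          if (i + np - 1L <= length(m) && all(m[i:(i + np - 1L)] == p)) {
            out <- c(out, paste(p, collapse = "_"))
            i <- i + np
          } else {
            out <- c(out, m[i])
            i <- i + 1L
          }
        }
        m <- out
      }
      m
    })
    corpus <- new("Corpus", messages = msgs, sourceLabel = corpus@sourceLabel)
  }
  list(corpus = corpus, merged = merged)
}

#' Select professional terms frequent enough to mine against
#'
#' Keeps the terms of `termList` that are in the vocabulary with corpus
#' frequency strictly greater than `minFreq` (default 1000, matching the
#' "count of over 1000" selection rule). The result is ordered by descending
#' frequency, ties lexicographic.
#'
#' @param vocab a [Vocabulary].
#' @param termList character vector of candidate professional terms (single
#'   tokens; run [mergeTerms()] first for multi-word concepts).
#' @param minFreq strict lower frequency bound.
#' @return character vector of selected terms.
#' @export
selectProfessionalTerms <- function(vocab, termList, minFreq = 1000L) {
  stopifnot(is(vocab, "Vocabulary"))
  if (minFreq < 0) stop("minFreq must be >= 0")
  termList <- unique(termList)
  f <- tokenFreq(vocab, termList)
  keep <- termList[f > minFreq & termList %in% vocab@tokens]
  keep[order(-tokenFreq(vocab, keep), keep, method = "radix")]
}

#' Construct a SeedPairSet
#'
#' @param professional,consumer character vectors of equal length (single
#'   tokens).
#' @param context optional character vector of free-text context.
#' @param provenance free-text description.
#' @return a [SeedPairSet].
#' @export
SeedPairSet <- function(professional = character(0),
                        consumer = character(0),
                        context = NA_character_,
                        provenance = NA_character_) {
  df <- data.frame(professional = as.character(professional),
                   consumer = as.character(consumer),
                   context = rep_len(as.character(context),
                                     length(professional)),
                   stringsAsFactors = FALSE)
  new("SeedPairSet", pairs = df, provenance = provenance)
}

#' @rdname seedPairs
setMethod("seedPairs", "SeedPairSet", function(x) x@pairs)

#' @export
setMethod("length", "SeedPairSet", function(x) nrow(x@pairs))

setMethod("show", "SeedPairSet", function(object) {
  cat(sprintf("SeedPairSet: %d pairs, %d distinct professional terms (%s)\n",
              nrow(object@pairs), length(unique(object@pairs$professional)),
              object@provenance))
})

#' Read / write seed-pair tables
#'
#' Tab-separated UTF-8 with header `professional<TAB>consumer<TAB>context`.
#' Reading warns about and drops duplicate (professional, consumer) rows and
#' errors (naming the line) on rows without 2 or 3 fields.
#'
#' @param path file path.
#' @return `readSeedPairs` returns a [SeedPairSet]; `writeSeedPairs` returns
#'   `path` invisibly.
#' @export
readSeedPairs <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop("empty seed-pair file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:2], c("professional", "consumer"))) {
    stop("line 1: expected header professional<TAB>consumer<TAB>context")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad) > 0) {
    stop(sprintf("line %d: malformed row (expected 2 or 3 tab-separated fields)",
                 bad[1] + 1L))
  }
  prof <- vapply(fields, `[`, character(1), 1)
  cons <- vapply(fields, `[`, character(1), 2)
  ctx <- vapply(fields, function(f) if (length(f) >= 3) f[3] else NA_character_,
                character(1))
  dup <- duplicated(paste(prof, cons, sep = "\r"))
  if (any(dup)) {
    warning(sprintf("%d duplicate pair(s) dropped", sum(dup)))
    prof <- prof[!dup]; cons <- cons[!dup]; ctx <- ctx[!dup]
  }
  SeedPairSet(prof, cons, ctx, provenance = path)
}

#' @rdname readSeedPairs
#' @param pairs a [SeedPairSet].
#' @export
writeSeedPairs <- function(pairs, path) {
  stopifnot(is(pairs, "SeedPairSet"))
  p <- pairs@pairs
  ctx <- ifelse(is.na(p$context), "", p$context)
  lines <- c("professional\tconsumer\tcontext",
             paste(p$professional, p$consumer, ctx, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a term list (one term per line, UTF-8)
#'
#' @param path file path.
#' @return `readTermList` returns a character vector; `writeTermList`
#'   returns `path` invisibly.
#' @export
readTermList <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  trimws(lines[nzchar(trimws(lines))])
}

#' @rdname readTermList
#' @param terms character vector.
#' @export
writeTermList <- function(terms, path) {
  writeLines(terms, path, useBytes = TRUE)
  invisible(path)
}

#' Merge two seed-pair sets, dropping duplicates
#'
#' @param x,y [SeedPairSet] objects.
#' @return a [SeedPairSet] containing the union of pairs.
#' @export
unionSeedPairs <- function(x, y) {
  stopifnot(is(x, "SeedPairSet"), is(y, "SeedPairSet"))
  df <- rbind(x@pairs, y@pairs)
  df <- df[!duplicated(df[, c("professional", "consumer")]), , drop = FALSE]
  rownames(df) <- NULL
  new("SeedPairSet", pairs = df,
      provenance = paste(x@provenance, y@provenance, sep = " + "))
}
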