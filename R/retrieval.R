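#' @include trainer.R
NULL

#' Rank candidate counterpart terms for a query
#'
#' Computes the cosine similarity between the query and every pool token in
#' the adapted space (or the raw pretrained space when `x` is an
#' [EmbeddingMatrix]) and returns the top `k`, sorted descending with the
#' deterministic tie-break (higher corpus frequency, then lexicographic).
#' The query itself and the placeholder tokens never appear among the
#' candidates. This is the list a curator reviews when expanding the
#' vocabulary.
#'
#' @param x a [ProjectionModel] or [EmbeddingMatrix].
#' @param query a vocabulary token.
#' @param k number of candidates requested.
#' @param pool candidate tokens; defaults to the full vocabulary minus the
#'   placeholders.
#' @return a [CandidateList].
#' @export
rankCandidates <- function(x, query, k = 10L, pool = NULL) {
  stopifnot(is(x, "ProjectionModel") || is(x, "EmbeddingMatrix"))
  if (k < 1) stop("k must be >= 1")
  vocab <- vocabulary(x)
  if (is.na(tokenIndex(vocab, query))) {
    stop("out-of-vocabulary query: ", query)
  }
  if (is.null(pool)) pool <- setdiff(vocab@tokens, specialTokens())
  if (length(pool) == 0) stop("empty candidate pool")
  pool <- setdiff(unique(pool), c(query, specialTokens()))
  if (length(pool) == 0) {
    return(new("CandidateList", query = query,
               entries = data.frame(token = character(0),
                                    similarity = numeric(0)),
               k = as.integer(k)))
  }
  idx <- .require_tokens(vocab, pool)
  if (is(x, "ProjectionModel")) {
    M <- .project_rows(x, idx)
    q <- projectToken(x, query)
  } else {
    M <- x@matrix[idx, , drop = FALSE]
    q <- x@matrix[tokenIndex(vocab, query), ]
  }
  nq <- sqrt(sum(q^2))
  if (nq == 0) stop("degenerate vector (zero norm)")
  sims <- drop(.normalize_rows(M, zero_ok = TRUE) %*% (q / nq))
  freq <- tokenFreq(vocab, pool)
  ord <- .order_candidates(sims, freq, pool)
  top <- utils::head(ord, k)
  new("CandidateList", query = query,
      entries = data.frame(token = pool[top], similarity = sims[top],
                           row.names = NULL),
      k = as.integer(k))
}

#' @rdname candidateEntries
setMethod("candidateEntries", "CandidateList", function(x) x@entries)

#' @export
setMethod("length", "CandidateList", function(x) nrow(x@entries))

setMethod("show", "CandidateList", function(object) {
  cat(sprintf("Top %d candidates for query '%s'\n", nrow(object@entries),
              object@query))
  e <- object@entries
  for (i in seq_len(min(nrow(e), 10L))) {
    cat(sprintf("  %2d  %-20s %.4f\n", i, e$token[i], e$similarity[i]))
  }
})

#' Entropy score for detecting consumer terms without a counterpart
#'
#' Normalizes the similarities between one consumer term and every
#' professional term in the dictionary into a probability distribution
#' (softmax) and returns its Shannon entropy in nats. A consumer term that
#' closely matches one professional term yields a peaked distribution and a
#' low entropy; a term similar to none of them yields a flat distribution
#' and a high entropy — a signal that a new professional concept may be
#' needed rather than a mapping to an existing one.
#'
#' @param x a [ProjectionModel] or [EmbeddingMatrix].
#' @param consumerTerm a vocabulary token.
#' @param professionalTerms at least two vocabulary tokens.
#' @param temperature softmax temperature (similarities are divided by it
#'   before exponentiation; 1 = plain softmax of raw cosines).
#' @return non-negative numeric scalar, at most `log(length(professionalTerms))`.
#' @export
newTermEntropy <- function(x, consumerTerm, professionalTerms,
                           temperature = 1) {
  stopifnot(is(x, "ProjectionModel") || is(x, "EmbeddingMatrix"))
  professionalTerms <- unique(professionalTerms)
  if (length(professionalTerms) < 2) {
    stop("at least 2 professional terms are required")
  }
  if (temperature <= 0) stop("temperature must be positive")
  sims <- vapply(professionalTerms, function(p) {
    cosineSimilarity(x, consumerTerm, p)
  }, numeric(1))
  z <- sims / temperature
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Export a human-review sheet of ranked candidates
#'
#' Writes a TSV with columns `query`, `rank`, `candidate`, `similarity` and
#' a blank `decision` column for reviewers, preserving candidate order.
#' Rows whose decision is filled with `accept` (or `yes`/`1`) can be read
#' back with [importReviewSheet()] as new seed pairs for the next training
#' iteration.
#'
#' @param x a [ProjectionModel] or [EmbeddingMatrix].
#' @param queries character vector of query tokens.
#' @param k candidates per query.
#' @param path output TSV path.
#' @param pool optional candidate pool passed to [rankCandidates()].
#' @return `path`, invisibly.
#' @export
exportReviewSheet <- function(x, queries, k = 10L, path, pool = NULL) {
  rows <- lapply(queries, function(q) {
    cl <- rankCandidates(x, q, k = k, pool = pool)
    e <- cl@entries
    if (nrow(e) == 0) return(NULL)
    data.frame(query = q, rank = seq_len(nrow(e)), candidate = e$token,
               similarity = sprintf("%.6f", e$similarity), decision = "")
  })
  df <- do.call(rbind, rows)
  lines <- c("query\trank\tcandidate\tsimilarity\tdecision",
             if (!is.null(df)) {
               paste(df$query, df$rank, df$candidate, df$similarity,
                     df$decision, sep = "\t")
             })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname exportReviewSheet
#' @return `importReviewSheet` returns a [SeedPairSet] of the accepted rows
#'   (query as professional term, candidate as consumer term).
#' @export
importReviewSheet <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop("empty review sheet: ", path)
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  fields <- fields[lengths(fields) >= 3]
  decision <- vapply(fields, function(f) {
    if (length(f) >= 5) tolower(trimws(f[5])) else ""
  }, character(1))
  acc <- decision %in% c("accept", "accepted", "yes", "y", "1", "true")
  SeedPairSet(professional = vapply(fields[acc], `[`, character(1), 1),
              consumer = vapply(fields[acc], `[`, character(1), 3),
              context = "review accepted",
              provenance = path)
}
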