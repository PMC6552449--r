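#' @include projection.R
NULL

#' Training configuration for projection fine-tuning
#'
#' @param learningRate step size (Adam default 0.003; for `optimizer = "sgd"`
#'   a much larger rate is usually needed because the surrogate differences
#'   are small when candidate cosines saturate).
#' @param epochs training epochs; each epoch refreshes the sorted-similarity
#'   targets once and runs one pass of mini-batch gradient descent.
#' @param batchSize mini-batch size.
#' @param poolSize number of most-frequent vocabulary tokens in the training
#'   candidate pool (all seed-pair members are always added).
#' @param seed integer seed controlling batch shuffling.
#' @param optimizer `"adam"` (default) or `"sgd"`. Adaptive per-parameter
#'   steps keep training responsive when the loss scale collapses as the
#'   top of a candidate list becomes nearly collinear with the query.
#' @param averageFraction fraction of the final epochs whose S snapshots are
#'   averaged into the returned model (Polyak-style tail averaging; 0
#'   disables it and returns the last iterate). Averaging damps the
#'   epoch-to-epoch oscillation of the surrogate objective and reduces
#'   overfitting of late iterates to the small seed-pair set.
#' @param margin offset added to the similarity target. The raw target is
#'   the similarity value at the synonym's desired rank among the *other*
#'   candidates; when candidate similarities saturate (many near-ties at
#'   the top of the list) reaching the target value exactly still loses
#'   the deterministic tie-break, so a small margin is required to actually
#'   claim the desired position. Targets are capped at 1.
#' @param orthoPenalty weight of the orthonormality regularizer
#'   \eqn{\lambda \|S S^\top - I\|_F^2} added to the surrogate objective.
#'   Pulling S toward a partial isometry makes the projection preserve
#'   within-subspace cosine geometry, so the adapted space keeps the raw
#'   embedding's retrieval quality where the seed pairs carry no signal;
#'   0 disables it.
#' @param lossVariant `"absolute"` or `"squared"`: how the monitored (not
#'   optimized) ranking loss aggregates rank displacements.
#' @param bidirectional also train with consumer terms as queries and their
#'   professional partners as synonyms.
#' @param updateEmbeddings test-only baseline flag: propagate gradients into
#'   a copy of E as well. Kept available because it demonstrates the
#'   overfitting the fixed-E design avoids; not a supported analysis mode.
#' @return a list of class `TrainConfig`.
#' @export
trainConfig <- function(learningRate = 0.003, epochs = 150L, batchSize = 32L,
                        poolSize = 1000L, seed = 1L,
                        lossVariant = c("absolute", "squared"),
                        optimizer = c("adam", "sgd"),
                        averageFraction = 0.5, margin = 0.01,
                        orthoPenalty = 0.03,
                        bidirectional = TRUE, updateEmbeddings = FALSE) {
  lossVariant <- match.arg(lossVariant)
  optimizer <- match.arg(optimizer)
  stopifnot(learningRate > 0, epochs >= 0, batchSize >= 1, poolSize >= 1,
            averageFraction >= 0, averageFraction <= 1, margin >= 0,
            orthoPenalty >= 0)
  structure(list(learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 poolSize = as.integer(poolSize), seed = as.integer(seed),
                 lossVariant = lossVariant, optimizer = optimizer,
                 averageFraction = averageFraction, margin = margin,
                 orthoPenalty = orthoPenalty,
                 bidirectional = bidirectional,
                 updateEmbeddings = updateEmbeddings),
            class = "TrainConfig")
}

#' Build the candidate pool for training or evaluation
#'
#' The `topN` most frequent vocabulary tokens plus every seed-pair member
#' and any extra tokens supplied, minus the placeholder tokens.
#'
#' @param vocab a [Vocabulary] (or object carrying one).
#' @param seedPairs optional [SeedPairSet] whose members are always included.
#' @param topN how many most-frequent tokens to include.
#' @param extra character vector of additional tokens to include.
#' @return character vector of pool tokens.
#' @export
buildCandidatePool <- function(vocab, seedPairs = NULL, topN = 1000L,
                               extra = character(0)) {
  if (!is(vocab, "Vocabulary")) vocab <- vocabulary(vocab)
  top <- utils::head(vocab@tokens, topN)  # tokens are stored frequency-sorted
  members <- character(0)
  if (!is.null(seedPairs)) {
    members <- unique(c(seedPairs@pairs$professional,
                        seedPairs@pairs$consumer))
  }
  pool <- unique(c(top, members, extra))
  setdiff(pool, specialTokens())
}

#' Assign desired ranks to labeled synonyms
#'
#' For each query term, its labeled synonyms Syn(query) receive the desired
#' ranks 1..k, ordered by corpus frequency (most frequent synonym first,
#' ties lexicographic): the supervision says the labeled synonyms should
#' occupy the top of the query's candidate list, most plausible first.
#'
#' @param seedPairs a [SeedPairSet].
#' @param vocab a [Vocabulary] covering every pair member.
#' @param pool candidate pool; defaults to [buildCandidatePool()].
#' @param bidirectional also create consumer-side queries whose synonyms are
#'   their professional partners.
#' @return a [RankingState].
#' @export
assignDesiredRanks <- function(seedPairs, vocab,
                               pool = buildCandidatePool(vocab, seedPairs),
                               bidirectional = TRUE) {
  stopifnot(is(seedPairs, "SeedPairSet"))
  if (!is(vocab, "Vocabulary")) vocab <- vocabulary(vocab)
  df <- seedPairs@pairs
  if (nrow(df) == 0) stop("no supervision: empty seed-pair set")
  members <- unique(c(df$professional, df$consumer))
  missing <- members[is.na(tokenIndex(vocab, members))]
  if (length(missing) > 0) {
    stop("pair member(s) out of vocabulary: ", paste(missing, collapse = ", "))
  }
  rel <- data.frame(query = df$professional, synonym = df$consumer)
  if (bidirectional) {
    rel <- rbind(rel, data.frame(query = df$consumer,
                                 synonym = df$professional))
  }
  rel <- rel[!duplicated(rel), , drop = FALSE]
  freq <- tokenFreq(vocab, rel$synonym)
  parts <- split(seq_len(nrow(rel)), rel$query)
  rel$desired_rank <- NA_integer_
  for (ix in parts) {
    ord <- order(-freq[ix], rel$synonym[ix], method = "radix")
    rel$desired_rank[ix[ord]] <- seq_along(ix)
  }
  rownames(rel) <- NULL
  new("RankingState", pairs = rel, pool = pool)
}

setMethod("show", "RankingState", function(object) {
  cat(sprintf("RankingState: %d (query, synonym) pairs, %d queries, pool %d\n",
              nrow(object@pairs), length(unique(object@pairs$query)),
              length(object@pool)))
})

# normalized projected vectors for the pool tokens (pool x s matrix)
.projected_pool <- function(model, pool) {
  vocab <- model@embedding@vocab
  idx <- .require_tokens(vocab, pool)
  P <- .normalize_rows(.project_rows(model, idx), zero_ok = TRUE)
  rownames(P) <- pool
  P
}

# descending similarity order with the deterministic tie-break:
# higher similarity, then higher corpus frequency, then lexicographic token
.order_candidates <- function(sims, freq, tokens) {
  order(-sims, -freq, tokens, method = "radix")
}

#' Sorted similarity values f(query) over the candidate pool
#'
#' The descending vector of projected-space cosine similarities between
#' `query` and every pool token other than itself; its k-th element is the
#' similarity value at rank k, the training target for a synonym whose
#' desired rank is k.
#'
#' @param model a [ProjectionModel].
#' @param state a [RankingState] (provides the pool).
#' @param query a vocabulary token.
#' @return named numeric vector, descending.
#' @export
sortedSimilarities <- function(model, state, query) {
  P <- .projected_pool(model, state@pool)
  .sorted_sims_from(P, model, state@pool, query,
                    tokenFreq(model@embedding@vocab, state@pool))
}

.sorted_sims_from <- function(P, model, pool, query, pool_freq) {
  q <- projectToken(model, query)
  nq <- sqrt(sum(q^2))
  if (nq == 0) stop("degenerate vector (zero norm)")
  sims <- drop(P %*% (q / nq))
  keep <- pool != query
  sims <- sims[keep]
  toks <- pool[keep]
  fr <- pool_freq[keep]
  ord <- .order_candidates(sims, fr, toks)
  stats::setNames(sims[ord], toks[ord])
}

#' Ranking loss of the current projected space
#'
#' Sums, over every (query, synonym) supervision pair, the displacement
#' between the synonym's current rank by projected-space cosine similarity
#' and its desired rank in the labeled set; zero exactly when every synonym
#' sits at its desired position. Not differentiable; used for monitoring
#' while the surrogate loss is optimized.
#'
#' @param model a [ProjectionModel].
#' @param state a [RankingState].
#' @param variant `"absolute"` (default) or `"squared"` displacement.
#' @return non-negative numeric scalar.
#' @export
rankingLoss <- function(model, state, variant = c("absolute", "squared")) {
  variant <- match.arg(variant)
  if (nrow(state@pairs) == 0) stop("no supervision: empty seed-pair set")
  P <- .projected_pool(model, state@pool)
  freq <- tokenFreq(model@embedding@vocab, state@pool)
  total <- 0
  for (q in unique(state@pairs$query)) {
    f <- .sorted_sims_from(P, model, state@pool, q, freq)
    rows <- state@pairs[state@pairs$query == q, , drop = FALSE]
    cur <- match(rows$synonym, names(f))
    if (anyNA(cur)) {
      stop("synonym(s) missing from candidate pool: ",
           paste(rows$synonym[is.na(cur)], collapse = ", "))
    }
    d <- cur - rows$desired_rank
    total <- total + if (variant == "absolute") sum(abs(d)) else sum(d^2)
  }
  total
}

# cosine + its gradients wrt the two projected vectors, and wrt S
.cos_grad <- function(model, a_row, b_row) {
  if (model@kind == "loglinear") {
    w <- model@S[1, ]
    u <- w * a_row
    v <- w * b_row
  } else {
    u <- drop(model@S %*% a_row)
    v <- drop(model@S %*% b_row)
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("degenerate vector (zero norm)")
  cval <- sum(u * v) / (nu * nv)
  dcdu <- v / (nu * nv) - cval * u / nu^2
  dcdv <- u / (nu * nv) - cval * v / nv^2
  list(c = cval, dcdu = dcdu, dcdv = dcdv)
}

#' Surrogate similarity-value loss for one supervision pair
#'
#' The ranking loss is not differentiable, so training minimizes
#' \eqn{\ell = (f(q)[k^*] - \cos_{proj}(q, r))^2}: the squared difference
#' between the similarity value currently sitting at the synonym's desired
#' rank \eqn{k^*} (a constant — no gradient flows through it) and the
#' synonym's own projected-space similarity. Driving the synonym's
#' similarity to the value at its desired position drags its rank toward
#' that position.
#'
#' @param model a [ProjectionModel].
#' @param state a [RankingState]; the synonym's desired rank and the pool
#'   are taken from it.
#' @param query,synonym a supervision pair present in `state`.
#' @param target optional precomputed target value f(query)[desired rank];
#'   computed from the current model when omitted.
#' @return non-negative numeric scalar.
#' @export
surrogateLoss <- function(model, state, query, synonym, target = NULL) {
  hit <- state@pairs$query == query & state@pairs$synonym == synonym
  if (!any(hit)) stop("pair not in ranking state: ", query, " / ", synonym)
  kstar <- state@pairs$desired_rank[hit][1]
  if (is.null(target)) {
    f <- sortedSimilarities(model, state, query)
    if (kstar > length(f)) stop("pool too small for desired rank ", kstar)
    target <- unname(f[kstar])
  }
  (target - cosineSimilarity(model, query, synonym))^2
}

#' Analytic gradient of the surrogate loss with respect to S
#'
#' @inheritParams surrogateLoss
#' @return list with elements `loss`, `grad` (same shape as S), `cos`, and
#'   — when the joint-update baseline needs them — `gradQuery` / `gradSynonym`
#'   (gradients with respect to the two E rows).
#' @export
surrogateGradient <- function(model, state, query, synonym, target = NULL) {
  hit <- state@pairs$query == query & state@pairs$synonym == synonym
  if (!any(hit)) stop("pair not in ranking state: ", query, " / ", synonym)
  kstar <- state@pairs$desired_rank[hit][1]
  if (is.null(target)) {
    f <- sortedSimilarities(model, state, query)
    if (kstar > length(f)) stop("pool too small for desired rank ", kstar)
    target <- unname(f[kstar])
  }
  vocab <- model@embedding@vocab
  idx <- .require_tokens(vocab, c(query, synonym))
  a <- model@embedding@matrix[idx[1], ]
  b <- model@embedding@matrix[idx[2], ]
  cg <- .cos_grad(model, a, b)
  coef <- -2 * (target - cg$c)
  if (model@kind == "loglinear") {
    grad <- matrix(coef * (cg$dcdu * a + cg$dcdv * b), nrow = 1)
    gq <- coef * (cg$dcdu * model@S[1, ])
    gs <- coef * (cg$dcdv * model@S[1, ])
  } else {
    grad <- coef * (outer(cg$dcdu, a) + outer(cg$dcdv, b))
    gq <- coef * drop(crossprod(model@S, cg$dcdu))
    gs <- coef * drop(crossprod(model@S, cg$dcdv))
  }
  list(loss = (target - cg$c)^2, grad = grad, cos = cg$c,
       gradQuery = gq, gradSynonym = gs)
}

# rank of the first relevant synonym per query, over the given pool
.first_relevant_ranks <- function(model, rel_df, pool) {
  P <- .projected_pool(model, pool)
  freq <- tokenFreq(model@embedding@vocab, pool)
  queries <- unique(rel_df$query)
  out <- stats::setNames(rep(Inf, length(queries)), queries)
  for (q in queries) {
    f <- .sorted_sims_from(P, model, pool, q, freq)
    syn <- rel_df$synonym[rel_df$query == q]
    pos <- match(syn, names(f))
    if (any(!is.na(pos))) out[q] <- min(pos, na.rm = TRUE)
  }
  out
}

#' Fine-tune the projection matrix on seed pairs
#'
#' Per epoch: (1) the projected vectors of the candidate pool and each
#' query's sorted similarity values are recomputed, fixing the surrogate
#' targets for this epoch; (2) one pass of mini-batch SGD on the summed
#' surrogate loss updates S (E stays bit-identical); (3) the monitored
#' ranking loss, mean surrogate loss and training MRR are appended to the
#' model's log. Fully deterministic given `config$seed`.
#'
#' @param model a [ProjectionModel].
#' @param seedPairs the supervision [SeedPairSet].
#' @param config a [trainConfig()].
#' @param heldout optional [SeedPairSet] whose MRR is logged per epoch
#'   (never trained on).
#' @return the fitted [ProjectionModel] (with training log).
#' @export
fitProjection <- function(model, seedPairs, config = trainConfig(),
                          heldout = NULL) {
  stopifnot(is(model, "ProjectionModel"), is(seedPairs, "SeedPairSet"))
  if (nrow(seedPairs@pairs) == 0) stop("no supervision: empty seed-pair set")
  vocab <- model@embedding@vocab
  pool <- buildCandidatePool(vocab, seedPairs, topN = config$poolSize)
  if (!is.null(heldout)) {
    pool <- unique(c(pool, buildCandidatePool(vocab, heldout, topN = 0L)))
  }
  state <- assignDesiredRanks(seedPairs, vocab, pool = pool,
                              bidirectional = config$bidirectional)
  if (config$epochs == 0L) return(model)

  freq <- tokenFreq(vocab, pool)
  pairs <- state@pairs
  n_pairs <- nrow(pairs)
  log_rows <- vector("list", config$epochs)

  adam <- config$optimizer == "adam"
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  avg_from <- config$epochs - floor(config$averageFraction * config$epochs) + 1L
  S_sum <- matrix(0, nrow(model@S), ncol(model@S))
  n_avg <- 0L
  mS <- vS <- matrix(0, nrow(model@S), ncol(model@S))
  if (config$updateEmbeddings) {
    mE <- vE <- matrix(0, nrow(model@embedding@matrix),
                       ncol(model@embedding@matrix))
  }
  step <- 0L

  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      # (1) refresh targets at the current S
      P <- .normalize_rows(
        .project_rows(model, .require_tokens(vocab, pool)), zero_ok = TRUE)
      rownames(P) <- pool
      targets <- numeric(n_pairs)
      for (q in unique(pairs$query)) {
        f <- .sorted_sims_from(P, model, pool, q, freq)
        rows <- which(pairs$query == q)
        ks <- pairs$desired_rank[rows]
        if (any(ks > length(f) - 1L)) {
          stop("pool too small for desired rank ", max(ks))
        }
        for (j in seq_along(rows)) {
          # target: the value at the desired rank among the OTHER
          # candidates, plus the tie-clearing margin
          others <- f[names(f) != pairs$synonym[rows[j]]]
          targets[rows[j]] <- min(1, unname(others[ks[j]]) + config$margin)
        }
      }

      # (2) one pass of mini-batch SGD on the surrogate loss
      ord <- sample.int(n_pairs)
      ep_loss <- 0
      i <- 1L
      qidx <- tokenIndex(vocab, pairs$query)
      sidx <- tokenIndex(vocab, pairs$synonym)
      while (i <= n_pairs) {
        batch <- ord[i:min(i + config$batchSize - 1L, n_pairs)]
        gS <- matrix(0, nrow(model@S), ncol(model@S))
        gE <- if (config$updateEmbeddings) {
          new.env(parent = emptyenv())
        } else NULL
        for (p in batch) {
          a <- model@embedding@matrix[qidx[p], ]
          b <- model@embedding@matrix[sidx[p], ]
          cg <- .cos_grad(model, a, b)
          diff <- targets[p] - cg$c
          ep_loss <- ep_loss + diff^2
          # gradient of the squared gap, renormalized by its magnitude:
          # keeps the pull O(1) while similarity gaps shrink toward the
          # tie-clearing margin instead of vanishing quadratically
          coef <- -2 * diff / (2 * abs(diff) + 1e-3)
          if (model@kind == "loglinear") {
            gS <- gS + coef * (cg$dcdu * a + cg$dcdv * b)
          } else {
            gS <- gS + coef * (outer(cg$dcdu, a) + outer(cg$dcdv, b))
          }
          if (config$updateEmbeddings) {
            w <- if (model@kind == "loglinear") model@S[1, ] else NULL
            ga <- if (is.null(w)) coef * drop(crossprod(model@S, cg$dcdu))
                  else coef * (cg$dcdu * w)
            gb <- if (is.null(w)) coef * drop(crossprod(model@S, cg$dcdv))
                  else coef * (cg$dcdv * w)
            for (upd in list(list(qidx[p], ga), list(sidx[p], gb))) {
              key <- as.character(upd[[1]])
              prev <- if (!is.null(gE[[key]])) gE[[key]] else 0
              gE[[key]] <- prev + upd[[2]]
            }
          }
        }
        gS <- gS / length(batch)
        if (config$orthoPenalty > 0 && model@kind == "projection") {
          gram <- model@S %*% t(model@S)
          diag(gram) <- diag(gram) - 1
          gS <- gS + 4 * config$orthoPenalty * gram %*% model@S
        }
        step <- step + 1L
        if (adam) {
          mS <- b1 * mS + (1 - b1) * gS
          vS <- b2 * vS + (1 - b2) * gS^2
          mhat <- mS / (1 - b1^step)
          vhat <- vS / (1 - b2^step)
          model@S <- model@S - config$learningRate * mhat /
            (sqrt(vhat) + adam_eps)
        } else {
          model@S <- model@S - config$learningRate * gS
        }
        if (config$updateEmbeddings) {
          gEm <- matrix(0, nrow(mE), ncol(mE))
          for (key in ls(gE)) {
            gEm[as.integer(key), ] <- gE[[key]] / length(batch)
          }
          if (adam) {
            mE <- b1 * mE + (1 - b1) * gEm
            vE <- b2 * vE + (1 - b2) * gEm^2
            model@embedding@matrix <- model@embedding@matrix -
              config$learningRate * (mE / (1 - b1^step)) /
              (sqrt(vE / (1 - b2^step)) + adam_eps)
          } else {
            model@embedding@matrix <- model@embedding@matrix -
              config$learningRate * gEm
          }
        }
        if (any(!is.finite(model@S))) {
          stop("training diverged (non-finite loss); reduce learningRate")
        }
        i <- i + config$batchSize
      }

      if (config$averageFraction > 0 && ep >= avg_from) {
        S_sum <- S_sum + model@S
        n_avg <- n_avg + 1L
      }

      # (3) monitoring
      rl <- rankingLoss(model, state, variant = config$lossVariant)
      tr_ranks <- .first_relevant_ranks(model, pairs, pool)
      tr_mrr <- mean(ifelse(is.finite(tr_ranks), 1 / tr_ranks, 0))
      ho_mrr <- NA_real_
      if (!is.null(heldout) && nrow(heldout@pairs) > 0) {
        ho_rel <- data.frame(query = heldout@pairs$professional,
                             synonym = heldout@pairs$consumer)
        ho_ranks <- .first_relevant_ranks(model, ho_rel, pool)
        ho_mrr <- mean(ifelse(is.finite(ho_ranks), 1 / ho_ranks, 0))
      }
      log_rows[[ep]] <- data.frame(epoch = ep,
                                   surrogate_loss = ep_loss / n_pairs,
                                   ranking_loss = rl, train_mrr = tr_mrr,
                                   heldout_mrr = ho_mrr)
    }
  })
  if (n_avg > 0L) model@S <- S_sum / n_avg
  model@log <- do.call(rbind, log_rows)
  validObject(model)
  model
}

#' One iteration of the semiautomatic review loop
#'
#' Reviewer-accepted candidate pairs are merged into the supervision set and
#' the model is refit on the union, optionally after enlarging the
#' projection with [expandProjection()] (the old rows are preserved).
#'
#' @param model the current [ProjectionModel].
#' @param seedPairs the current supervision [SeedPairSet].
#' @param acceptedPairs newly accepted pairs (a [SeedPairSet]; may be empty).
#' @param config a [trainConfig()].
#' @param expandTo optional new projection size passed to
#'   [expandProjection()] before refitting.
#' @param heldout optional held-out pairs for logging.
#' @return list with the refit `model` and the union `pairs`.
#' @export
iterateWithReview <- function(model, seedPairs, acceptedPairs,
                              config = trainConfig(), expandTo = NULL,
                              heldout = NULL) {
  union <- unionSeedPairs(seedPairs, acceptedPairs)
  if (!is.null(expandTo)) {
    model <- expandProjection(model, expandTo, seed = config$seed)
  }
  list(model = fitProjection(model, union, config, heldout = heldout),
       pairs = union)
}

#' Write a training log as JSON lines
#'
#' One JSON record per epoch with fields epoch, surrogate_loss,
#' ranking_loss, train_mrr, heldout_mrr.
#'
#' @param model a fitted [ProjectionModel].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrainingLog <- function(model, path) {
  stopifnot(is(model, "ProjectionModel"))
  lg <- model@log
  lines <- vapply(seq_len(nrow(lg)), function(i) {
    jsonlite::toJSON(as.list(lg[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
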