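#' @include corpus.R
NULL

#' Configuration for the synthetic health-forum corpus generator
#'
#' The generator emulates the statistical structure the mining method
#' exploits in real forum text: a professional term and its consumer
#' variants are mentioned inside the same concept-specific context
#' distribution (related diseases, symptoms and drugs in real data), on a
#' background of high-frequency general tokens. Tokens are synthetic symbols
#' (`P007`, `C007_1`, `X007_3`, ...) so the planted gold structure stays
#' auditable.
#'
#' @param nConcepts number of professional concepts.
#' @param synonymsPerConcept consumer variants per concept (>= 1).
#' @param vocabSize upper bound on the generated vocabulary; must admit all
#'   concept, synonym and context tokens.
#' @param nMessages messages to generate.
#' @param messageLength tokens per message.
#' @param contextSize dedicated context tokens per concept.
#' @param noiseRate fraction of context slots drawn from the global Zipfian
#'   background instead of the concept's own context set, in `[0, 1)`.
#' @param typoRate probability that a consumer mention is emitted as its
#'   fixed character-perturbed variant, in `[0, 1)`.
#' @param orphanRate fraction of consumer tokens generated with no
#'   professional partner (their context sets overlap no concept's), in
#'   `[0, 1)`.
#' @param nBackground size of the Zipfian background vocabulary.
#' @param seed integer seed; the generator is fully reproducible.
#' @return a list of class `GeneratorConfig`.
#' @export
generatorConfig <- function(nConcepts = 20L, synonymsPerConcept = 2L,
                            vocabSize = 1000L, nMessages = 5000L,
                            messageLength = 12L, contextSize = 8L,
                            noiseRate = 0.2, typoRate = 0.05,
                            orphanRate = 0.1, nBackground = 200L,
                            seed = 1L) {
  cfg <- list(nConcepts = as.integer(nConcepts),
              synonymsPerConcept = as.integer(synonymsPerConcept),
              vocabSize = as.integer(vocabSize),
              nMessages = as.integer(nMessages),
              messageLength = as.integer(messageLength),
              contextSize = as.integer(contextSize),
              noiseRate = noiseRate, typoRate = typoRate,
              orphanRate = orphanRate,
              nBackground = as.integer(nBackground),
              seed = as.integer(seed))
  if (cfg$synonymsPerConcept < 1) stop("synonymsPerConcept must be >= 1")
  for (r in c("noiseRate", "typoRate", "orphanRate")) {
    if (cfg[[r]] < 0 || cfg[[r]] >= 1) stop(r, " must lie in [0, 1)")
  }
  if (cfg$messageLength < 2) stop("messageLength must be >= 2")
  n_orphan <- round(cfg$orphanRate * cfg$nConcepts * cfg$synonymsPerConcept)
  need <- cfg$nConcepts * (1L + cfg$synonymsPerConcept) +
    (cfg$nConcepts + n_orphan) * cfg$contextSize + n_orphan
  if (need > cfg$vocabSize) {
    stop(sprintf(paste0("infeasible config: nConcepts*(1+synonymsPerConcept)",
                        " + context vocabulary = %d exceeds vocabSize = %d"),
                 need, cfg$vocabSize))
  }
  class(cfg) <- "GeneratorConfig"
  cfg
}

#' Generate a synthetic corpus with planted professional/consumer pairs
#'
#' Each concept i owns a professional token `P_i`, consumer tokens `C_i_j`
#' and a dedicated context set `X_i`. A message mentions one entity (the
#' professional token with probability 1/2, else one consumer variant) at a
#' random position; the remaining slots are filled from `X_i`, except a
#' `noiseRate` fraction drawn from a global Zipfian background. Consumer
#' mentions are emitted as a fixed typo variant (`C_i_j~`) with probability
#' `typoRate`. A fraction `orphanRate` of the consumer tokens are orphans:
#' they get their own context sets overlapping no concept's and no
#' professional partner, so they are absent from the gold pairs.
#'
#' @param config a [generatorConfig()].
#' @return list with components `corpus` ([Corpus]), `pairs` (the gold
#'   [SeedPairSet]; `nConcepts * synonymsPerConcept * (1 - orphanRate)`
#'   rounded, pairs), `professionalTerms` (character), `orphans` (character:
#'   consumer tokens with no partner), and `typoPairs` (a [SeedPairSet] of
#'   typo-variant synonyms that actually occurred in the corpus).
#' @export
generateCorpus <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "GeneratorConfig"))
  withr::with_seed(config$seed, .generate_corpus_impl(config))
}

.generate_corpus_impl <- function(cfg) {
  nC <- cfg$nConcepts
  nS <- cfg$synonymsPerConcept
  n_pairs_total <- nC * nS
  n_orphan <- round(cfg$orphanRate * n_pairs_total)

  prof <- sprintf("P%03d", seq_len(nC))
  cons <- matrix(sprintf("C%03d_%d", rep(seq_len(nC), each = nS),
                         rep(seq_len(nS), nC)),
                 nrow = nC, byrow = TRUE)
  typo <- matrix(paste0(cons, "~"), nrow = nC)
  ctx <- lapply(seq_len(nC), function(i) {
    sprintf("X%03d_%d", i, seq_len(cfg$contextSize))
  })

  # orphan consumer tokens replace the LAST n_orphan (concept, synonym)
  # slots so the partnered pair count is exactly n_pairs_total - n_orphan
  slots <- expand.grid(j = seq_len(nS), i = seq_len(nC))[, c("i", "j")]
  orphan_slots <- utils::tail(seq_len(n_pairs_total), n_orphan)
  orphan_tokens <- sprintf("O%03d", seq_len(n_orphan))
  orphan_ctx <- lapply(seq_len(n_orphan), function(k) {
    sprintf("XO%02d_%d", k, seq_len(cfg$contextSize))
  })
  is_orphan <- matrix(FALSE, nrow = nC, ncol = nS)
  for (k in seq_along(orphan_slots)) {
    sl <- slots[orphan_slots[k], ]
    is_orphan[sl$i, sl$j] <- TRUE
  }

  bg <- sprintf("B%03d", seq_len(cfg$nBackground))
  bg_prob <- (1 / seq_len(cfg$nBackground))
  bg_prob <- bg_prob / sum(bg_prob)

  # one sampling unit per concept plus one per orphan token
  n_units <- nC + n_orphan
  unit <- sample.int(n_units, cfg$nMessages, replace = TRUE)
  L <- cfg$messageLength

  msgs <- vector("list", cfg$nMessages)
  typo_seen <- character(0)
  orphan_idx <- 0L
  for (m in seq_len(cfg$nMessages)) {
    u <- unit[m]
    if (u <= nC) {
      if (stats::runif(1) < 0.5) {
        mention <- prof[u]
      } else {
        j <- sample.int(nS, 1L)
        if (is_orphan[u, j]) {
          # this slot's consumer token is an orphan; fall back to the
          # professional mention so concept structure stays intact
          mention <- prof[u]
        } else {
          mention <- cons[u, j]
          if (stats::runif(1) < cfg$typoRate) {
            mention <- typo[u, j]
            typo_seen <- union(typo_seen, mention)
          }
        }
      }
      pool <- ctx[[u]]
    } else {
      mention <- orphan_tokens[u - nC]
      pool <- orphan_ctx[[u - nC]]
    }
    body <- ifelse(stats::runif(L - 1L) < cfg$noiseRate,
                   sample(bg, L - 1L, replace = TRUE, prob = bg_prob),
                   sample(pool, L - 1L, replace = TRUE))
    pos <- sample.int(L, 1L)
    msg <- append(body, mention, after = pos - 1L)
    msgs[[m]] <- msg
  }

  keep <- !t(is_orphan)  # column-major over (j, i) = slot order
  gold <- SeedPairSet(professional = rep(prof, each = nS)[c(keep)],
                      consumer = t(cons)[keep],
                      context = "planted",
                      provenance = "synthetic generator")
  tp <- t(typo)[keep]
  tprof <- rep(prof, each = nS)[c(keep)]
  occurred <- tp %in% typo_seen
  typo_pairs <- SeedPairSet(professional = tprof[occurred],
                            consumer = tp[occurred],
                            context = "typo variant",
                            provenance = "synthetic generator")
  list(corpus = Corpus(msgs, sourceLabel = "synthetic"),
       pairs = gold,
       professionalTerms = prof,
       orphans = orphan_tokens,
       typoPairs = typo_pairs)
}

#' Split seed pairs into training and evaluation sets, concept-wise
#'
#' All synonyms of one professional term land on the same side, so the
#' evaluation measures generalization to unseen concepts rather than
#' completion of partially seen ones.
#'
#' @param pairs a [SeedPairSet].
#' @param trainFraction fraction of concepts assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return list with [SeedPairSet] components `train` and `test`.
#' @export
splitPairs <- function(pairs, trainFraction = 0.7, seed = 1L) {
  stopifnot(is(pairs, "SeedPairSet"))
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must lie strictly between 0 and 1")
  }
  concepts <- unique(pairs@pairs$professional)
  n_train <- round(trainFraction * length(concepts))
  if (n_train == 0 || n_train == length(concepts)) {
    stop("split would leave one side empty")
  }
  train_c <- withr::with_seed(as.integer(seed), {
    sample(concepts, n_train)
  })
  df <- pairs@pairs
  tr <- df$professional %in% train_c
  mk <- function(d) {
    rownames(d) <- NULL
    new("SeedPairSet", pairs = d, provenance = pairs@provenance)
  }
  list(train = mk(df[tr, , drop = FALSE]), test = mk(df[!tr, , drop = FALSE]))
}
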