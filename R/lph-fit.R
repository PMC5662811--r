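# Fitting the pair-aware supervised topic model by collapsed Gibbs
# sampling. With an empty pair table the model is exactly Labeled LDA:
# every herb is a singleton sampling unit and the two fits share one code
# path (and therefore one random trajectory at equal seed).

#' Hyperparameter configuration for model fitting
#'
#' @param alpha Dirichlet prior on the per-prescription function mixture;
#'   `NULL` (default) resolves to `50 / K` at fit time.
#' @param eta symmetric Dirichlet prior on the per-function herb
#'   multinomial (default 0.1).
#' @param nIterations number of full Gibbs sweeps (default 500).
#' @param seed RNG seed controlling initialization and sampling; a fixed
#'   seed gives bit-identical final counts.
#' @param estimateMode `"final_state"` estimates beta/theta from the last
#'   sweep's counts; `"mean_last_S"` averages the estimates over the last
#'   `S` sweeps.
#' @param S averaging window for `"mean_last_S"` (default 100).
#' @param gamma accepted for interface completeness; the pair indicator
#'   of every herb is observed from the mined pair table, so the Bernoulli
#'   prior is never used.
#' @return list of class `"lphConfig"`
#' @export
lphConfig <- function(alpha = NULL, eta = 0.1, nIterations = 500L,
                      seed = 1L,
                      estimateMode = c("final_state", "mean_last_S"),
                      S = 100L, gamma = NULL) {
  estimateMode <- match.arg(estimateMode)
  stopifnot(is.null(alpha) || alpha > 0, eta > 0, nIterations >= 1,
            S >= 1)
  structure(list(alpha = alpha, eta = eta,
                 nIterations = as.integer(nIterations),
                 seed = as.integer(seed), estimateMode = estimateMode,
                 S = as.integer(S), gamma = gamma),
            class = "lphConfig")
}

#' Match mined pairs inside one prescription
#'
#' Greedy matching by mining rank: pairs are scanned in `cor`-descending
#' order; whenever both member herbs are present in the prescription and
#' neither is already matched, the two are marked as one pair unit. Every
#' herb belongs to at most one pair; all remaining herbs are singletons.
#'
#' @param prescription one element of [prescriptions()] (components
#'   `herbIds`, `doses`, ...)
#' @param pairTable a [PairTable-class]; its `pairs` slot is already
#'   sorted by `cor` descending
#' @return list with `x` (integer 0/1 per herb position: 1 = in a pair)
#'   and `partner` (integer herb position of the partner, NA when `x = 0`)
#' @export
assignPairs <- function(prescription, pairTable) {
  ids <- prescription$herbIds
  n <- length(ids)
  x <- integer(n)
  partner <- rep(NA_integer_, n)
  pp <- pairTable@pairs
  if (nrow(pp)) {
    pos <- match(pp$id_i, ids)
    pos2 <- match(pp$id_j, ids)
    hit <- which(!is.na(pos) & !is.na(pos2))
    for (r in hit) {
      i <- pos[r]; j <- pos2[r]
      if (x[i] == 0L && x[j] == 0L) {
        x[i] <- x[j] <- 1L
        partner[i] <- j
        partner[j] <- i
      }
    }
  }
  list(x = x, partner = partner)
}

# Decompose a corpus into sampling units given a pair table.
# Units are emitted per prescription in herb order; a pair unit appears
# at the position of its first member.
.corpusUnits <- function(corpus, pairTable) {
  h1 <- integer(); h2 <- integer(); pres <- integer()
  presId <- character()
  plist <- corpus@prescriptions
  for (pi in seq_along(plist)) {
    p <- plist[[pi]]
    pa <- assignPairs(p, pairTable)
    for (i in seq_along(p$herbIds)) {
      if (pa$x[i] == 1L && pa$partner[i] < i) next  # emitted with partner
      h1 <- c(h1, p$herbIds[i])
      h2 <- c(h2, if (pa$x[i] == 1L) p$herbIds[pa$partner[i]] else
        NA_integer_)
      pres <- c(pres, pi)
      presId <- c(presId, p$id)
    }
  }
  list(h1 = h1, h2 = h2, pres = pres, presId = presId)
}

.activeLabelSets <- function(corpus) {
  lapply(corpus@prescriptions, function(p) {
    if (length(p$labels) == 0)
      stop("prescription '", p$id, "' has no labels; ",
           "training requires at least one active label")
    as.integer(sort(unique(p$labels)))
  })
}

#' Initialize the Gibbs sampler state
#'
#' Each sampling unit (singleton herb or matched pair) receives a
#' uniformly random label from its prescription's active label set; the
#' count arrays are built to match. Uses `config$seed`, so the initial
#' state is reproducible.
#'
#' @param corpus a labeled [HerbCorpus-class]
#' @param pairTable a [PairTable-class] (possibly [emptyPairTable()])
#' @param config an [lphConfig()]
#' @return list of class `"lphState"` with the unit decomposition, the
#'   assignment vector `z` (1-based labels) and count arrays `nkh`
#'   (K x V), `nk`, `npk` (N x K), `np`
#' @export
lphInitState <- function(corpus, pairTable, config = lphConfig()) {
  units <- .corpusUnits(corpus, pairTable)
  active <- .activeLabelSets(corpus)
  K <- nLabels(corpus); V <- nHerbs(corpus)
  N <- nPrescriptions(corpus)
  set.seed(config$seed)
  z <- vapply(seq_along(units$h1), function(u) {
    A <- active[[units$pres[u]]]
    A[sample.int(length(A), 1L)]
  }, 0L)
  st <- list(units = units, z = z, active = active,
             K = K, V = V, N = N,
             config = config,
             counts = .countsFromAssignments(units, z, K, V, N))
  class(st) <- "lphState"
  st
}

.countsFromAssignments <- function(units, z, K, V, N) {
  nkh <- matrix(0L, K, V)
  nk <- integer(K)
  npk <- matrix(0L, N, K)
  np <- integer(N)
  for (u in seq_along(z)) {
    k <- z[u]; p <- units$pres[u]
    size <- if (is.na(units$h2[u])) 1L else 2L
    nkh[k, units$h1[u]] <- nkh[k, units$h1[u]] + 1L
    if (size == 2L) nkh[k, units$h2[u]] <- nkh[k, units$h2[u]] + 1L
    nk[k] <- nk[k] + size
    npk[p, k] <- npk[p, k] + size
    np[p] <- np[p] + size
  }
  list(nkh = nkh, nk = nk, npk = npk, np = np)
}

#' Run Gibbs sweeps on a sampler state
#'
#' Resamples every unit's function assignment from its collapsed
#' conditional (restricted to the prescription's active labels),
#' decrementing the unit's counts before the draw and re-incrementing
#' after. Consumes R's RNG stream; call after [lphInitState()] (which
#' seeds it) or seed manually for reproducibility.
#'
#' @param state an `"lphState"` from [lphInitState()]
#' @param nSweeps number of full sweeps (default 1)
#' @return the updated state
#' @export
lphGibbsSweep <- function(state, nSweeps = 1L) {
  cfg <- state$config
  alpha <- if (is.null(cfg$alpha)) 50 / state$K else cfg$alpha
  res <- cpp_lph_gibbs(
    state$units$h1 - 1L,
    ifelse(is.na(state$units$h2), -1L, state$units$h2 - 1L),
    state$units$pres - 1L,
    state$z - 1L,
    lapply(state$active, function(a) a - 1L),
    state$K, state$V, state$N,
    alpha, cfg$eta, as.integer(nSweeps), 0L, 0L)
  state$z <- res$z + 1L
  state$counts <- list(nkh = res$nkh, nk = res$nk,
                       npk = res$npk, np = res$np)
  state
}

#' Conditional assignment distribution of one sampling unit
#'
#' The normalized collapsed conditional over the prescription's active
#' labels for unit `u`, computed exactly as during a sweep (counts
#' excluding the unit itself). Exposed mainly for inspection and testing.
#'
#' @param state an `"lphState"`
#' @param u unit index
#' @return named numeric vector of probabilities over the active labels
#' @export
lphUnitConditional <- function(state, u) {
  cfg <- state$config
  alpha <- if (is.null(cfg$alpha)) 50 / state$K else cfg$alpha
  cts <- state$counts
  k <- state$z[u]; p <- state$units$pres[u]
  h1 <- state$units$h1[u]; h2 <- state$units$h2[u]
  size <- if (is.na(h2)) 1L else 2L
  nkh <- cts$nkh; nk <- cts$nk; npk <- cts$npk
  nkh[k, h1] <- nkh[k, h1] - 1L
  if (size == 2L) nkh[k, h2] <- nkh[k, h2] - 1L
  nk[k] <- nk[k] - size
  npk[p, k] <- npk[p, k] - size
  A <- state$active[[p]]
  pr <- cpp_unit_conditional(nkh, nk, npk, cts$np[p] - size,
                             h1 - 1L, if (size == 2L) h2 - 1L else -1L,
                             p - 1L, A - 1L, alpha, cfg$eta, state$V)
  setNames(as.numeric(pr), as.character(A))
}

#' Fit the pair-aware supervised topic model
#'
#' Initializes assignments uniformly over each prescription's active
#' labels, runs `config$nIterations` collapsed Gibbs sweeps, and
#' estimates the function-herb multinomials
#' `beta[k, h] = (n_kh + eta) / (n_k + eta * V)` and the prescription
#' mixtures `theta[p, k] = (n_pk + alpha) / (n_p + alpha * Kp)` from the
#' final state (or their average over the last `S` sweeps).
#'
#' @param corpus a labeled [HerbCorpus-class]
#' @param pairTable a [PairTable-class]; use [emptyPairTable()] (or
#'   [fitLabeledLDA()]) for the Labeled-LDA special case
#' @param config an [lphConfig()]
#' @param tracePairs if > 0, record each pair unit's assignment over the
#'   last `tracePairs` sweeps into the model's `pairTrace` slot
#' @return an [LPHModel-class]
#' @export
fitLPH <- function(corpus, pairTable = emptyPairTable(),
                   config = lphConfig(), tracePairs = 0L) {
  units <- .corpusUnits(corpus, pairTable)
  active <- .activeLabelSets(corpus)
  K <- nLabels(corpus); V <- nHerbs(corpus)
  N <- nPrescriptions(corpus)
  alpha <- if (is.null(config$alpha)) 50 / K else config$alpha
  set.seed(config$seed)
  z <- vapply(seq_along(units$h1), function(u) {
    A <- active[[units$pres[u]]]
    A[sample.int(length(A), 1L)]
  }, 0L)
  avgS <- if (config$estimateMode == "mean_last_S")
    min(config$S, config$nIterations) else 0L
  res <- cpp_lph_gibbs(
    units$h1 - 1L, ifelse(is.na(units$h2), -1L, units$h2 - 1L),
    units$pres - 1L, z - 1L,
    lapply(active, function(a) a - 1L),
    K, V, N, alpha, config$eta, config$nIterations,
    as.integer(avgS), as.integer(tracePairs))

  if (avgS > 0) {
    beta <- res$betaAvg
    beta <- beta / rowSums(beta)  # guard roundoff at the 1e-16 level
    theta <- res$thetaAvg
    rs <- rowSums(theta)
    theta <- theta / ifelse(rs > 0, rs, 1)
  } else {
    beta <- (res$nkh + config$eta) / (res$nk + config$eta * V)
    theta <- matrix(0, N, K)
    for (p in seq_len(N)) {
      A <- active[[p]]
      theta[p, A] <- (res$npk[p, A] + alpha) /
        (res$np[p] + alpha * length(A))
    }
  }
  dimnames(beta) <- list(corpus@labelNames, herbNames(corpus))
  dimnames(theta) <- list(vapply(corpus@prescriptions, `[[`, "", "id"),
                          corpus@labelNames)

  trace <- res$pairTrace + 1L
  if (ncol(trace) > 0) {
    pu <- res$pairUnits + 1L
    nm <- herbNames(corpus)
    colnames(trace) <- paste0(units$presId[pu], ":",
                              nm[units$h1[pu]], "+", nm[units$h2[pu]])
  }

  new("LPHModel", beta = beta, theta = theta,
      counts = list(nkh = res$nkh, nk = res$nk,
                    npk = res$npk, np = res$np),
      config = c(unclass(config), list(alphaResolved = alpha)),
      labelNames = corpus@labelNames, herbNames = herbNames(corpus),
      pairTable = pairTable, pairTrace = trace)
}

#' Fit the Labeled-LDA special case
#'
#' Identical to `fitLPH(corpus, emptyPairTable(), config)` draw-for-draw:
#' with no pairs every herb is its own sampling unit.
#'
#' @inheritParams fitLPH
#' @return an [LPHModel-class]
#' @export
fitLabeledLDA <- function(corpus, config = lphConfig()) {
  fitLPH(corpus, emptyPairTable(), config)
}
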