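# Shared fixtures and independent oracles used across the suite.

# The classic four-herb exterior-releasing formula with its pharmacopoeial
# dosage ranges and attribute terms.
maHuangTangTable <- function() {
  data.frame(
    name = c("Ephedrae Herba", "Cinnamomi Ramulus",
             "Armeniacae Semen Amarum", "Glycyrrhizae Radix"),
    doseMin = c(2, 3, 4.5, 1.5),
    doseMax = c(9, 9, 9, 9),
    natureFlavor = c("spicy;slightly bitter;warm", "spicy;sweet;warm",
                     "bitter;warm", "sweet;neutral"),
    channelTropism = c("lungs;bladder", "heart;lungs;bladder",
                       "lungs;large intestine",
                       "heart;lungs;spleen;stomach"),
    efficiency = c("inducing perspiration;relieving asthma",
                   "inducing perspiration;warming the interior",
                   "relieving asthma;stopping cough",
                   "tonifying qi;detoxifying"),
    stringsAsFactors = FALSE)
}

maHuangTangCorpus <- function() {
  makeCorpus(
    list(list(id = "Ma Huang Tang",
              herbs = c("Ephedrae Herba", "Cinnamomi Ramulus",
                        "Armeniacae Semen Amarum", "Glycyrrhizae Radix"),
              doses = c(9, 6, 6, 3),
              labels = "relieving exterior syndrome")),
    herbTable = maHuangTangTable())
}

# Tiny hand-enumerable corpus builder: `spec` is a list of character
# herb-name vectors, `labels` a parallel list of label vectors.
tinyCorpus <- function(spec, labels = NULL, doses = NULL) {
  if (is.null(labels)) labels <- rep(list("L1"), length(spec))
  makeCorpus(lapply(seq_along(spec), function(i)
    list(id = paste0("p", i), herbs = spec[[i]],
         doses = if (is.null(doses)) rep(5, length(spec[[i]]))
                 else doses[[i]],
         labels = labels[[i]])))
}

# ---- independent brute-force pair-mining oracle -------------------------
# Plain double loops over the herb vocabulary, written from the score
# definitions; no shared code with the package implementation.
bruteForcePairRanking <- function(corpus, a = 0.5, b = 0.5) {
  nm <- herbNames(corpus)
  V <- length(nm)
  N <- nPrescriptions(corpus)
  present <- matrix(FALSE, N, V)
  for (i in seq_len(N))
    present[i, prescriptions(corpus)[[i]]$herbIds] <- TRUE
  rows <- list()
  for (i in seq_len(V - 1)) {
    for (j in (i + 1):V) {
      joint <- sum(present[, i] & present[, j])
      if (joint == 0) next
      support <- joint / N
      pi <- sum(present[, i]) / N
      pj <- sum(present[, j]) / N
      dependency <- support / (pi * pj)
      rows[[length(rows) + 1L]] <- data.frame(
        herb_i = nm[i], herb_j = nm[j],
        support = support, dependency = dependency,
        cor = a * support + b * dependency, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$cor, -out$support, out$herb_i, out$herb_j), ,
      drop = FALSE]
}

# Random small corpus for oracle-equivalence checks.
randomTinyCorpus <- function(seed, maxN = 200L) {
  set.seed(seed)
  V <- sample(6:15, 1)
  N <- sample(5:maxN, 1)
  herbs <- sprintf("h%02d", seq_len(V))
  makeCorpus(lapply(seq_len(N), function(i) {
    n <- sample(2:min(6, V), 1)
    list(id = paste0("r", i), herbs = sample(herbs, n),
         doses = rep(3, n), labels = "L1")
  }))
}

# ---- independent TFIDF oracle -------------------------------------------
bruteForceTfidf <- function(corpus) {
  nm <- herbNames(corpus)
  h <- herbTable(corpus)
  N <- nPrescriptions(corpus)
  dfreq <- sapply(seq_along(nm), function(v)
    sum(sapply(prescriptions(corpus), function(p) v %in% p$herbIds)))
  t(sapply(prescriptions(corpus), function(p) {
    dstar <- p$doses / (h$doseMax[p$herbIds] + h$doseMin[p$herbIds])
    Fw <- dstar / sum(dstar)
    out <- numeric(length(nm))
    for (t in seq_along(p$herbIds))
      out[p$herbIds[t]] <- Fw[t] * log(N / dfreq[p$herbIds[t]])
    out
  }))
}

# ---- generator presets frozen for the suite -----------------------------
miningFixtureConfig <- function(seed = 5) {
  generatorConfig(K = 4, V = 40, N = 2000, meanHerbs = 5,
    betaConcentration = 10, offBlockConcentration = 10, truthSimN = 0,
    plantedPairs = data.frame(
      herb_i = c(3L, 11L, 22L), herb_j = c(7L, 15L, 30L),
      label = c(1L, 2L, 3L), boost = c(20, 20, 20)),
    seed = seed)
}

orderingFixtureConfig <- function(seed = 1) {
  generatorConfig(K = 5, V = 400, N = 200, meanHerbs = 8,
    betaConcentration = 10, offBlockConcentration = 0.02,
    truthSimN = 0, seed = seed)
}
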