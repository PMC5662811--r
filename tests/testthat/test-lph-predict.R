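# Hand-built model helper: K labels x V herbs with given beta rows and
# matching synthetic count arrays (counts chosen so that the smoothed
# ratio reproduces beta closely).
mockModel <- function(beta, herbNames, labelNames, eta = 1e-6) {
  scale <- 1e6
  nkh <- round(beta * scale)
  counts <- list(nkh = nkh, nk = rowSums(nkh),
                 npk = matrix(0L, 0, nrow(beta)), np = integer(0))
  new("LPHModel", beta = beta / rowSums(beta),
      theta = matrix(numeric(0), 0, nrow(beta)),
      counts = counts,
      config = list(eta = eta, alpha = 1, nIterations = 0L, seed = 1L,
                    estimateMode = "final_state", S = 0L),
      labelNames = labelNames, herbNames = herbNames,
      pairTable = emptyPairTable(),
      pairTrace = matrix(integer(0), 0, 0))
}

test_that("identical beta rows give identical scores; single herb ranks by beta", {
  herbs <- c("A", "B", "C")
  beta <- matrix(1 / 3, 2, 3, dimnames = list(c("L1", "L2"), herbs))
  m <- mockModel(beta, herbs, c("L1", "L2"))
  sc <- scoreLabels(m, list(herbs = c("A", "C")))
  expect_equal(sc[["L1"]], sc[["L2"]])

  beta2 <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6))
  m2 <- mockModel(beta2, herbs, c("L1", "L2"))
  sc2 <- scoreLabels(m2, list(herbs = "A"))
  expect_equal(order(as.numeric(sc2), decreasing = TRUE),
               order(beta2[, 1], decreasing = TRUE))
})

test_that("unknown herbs are skipped with a warning, all-unknown errors", {
  herbs <- c("A", "B")
  m <- mockModel(matrix(0.5, 2, 2), herbs, c("L1", "L2"))
  expect_warning(scoreLabels(m, list(herbs = c("A", "nope"))), "unknown")
  expect_error(suppressWarnings(scoreLabels(m, list(herbs = "nope"))),
               "no prescription herb")
})

test_that("thresholding is monotone and respects the raw product scale", {
  set.seed(5)
  sc <- structure(setNames(log(runif(8, 1e-12, 1e-2)), letters[1:8]),
                  class = "labelScores")
  expect_length(predictLabels(sc, exp(max(as.numeric(sc))) * 1.01), 0L)
  grid <- 10^seq(-12, -2, by = 0.5)
  sizes <- vapply(grid, function(T) length(predictLabels(sc, T)), 0L)
  expect_true(all(diff(sizes) <= 0))
  # predicted sets are nested as T grows
  sets <- lapply(grid, function(T) predictLabels(sc, T))
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("label permutation permutes scores equivariantly", {
  herbs <- c("A", "B", "C", "D")
  set.seed(2)
  beta <- matrix(rgamma(12, 1), 3, 4,
                 dimnames = list(paste0("L", 1:3), herbs))
  beta <- beta / rowSums(beta)
  perm <- c(3, 1, 2)
  m1 <- mockModel(beta, herbs, paste0("L", 1:3))
  m2 <- mockModel(beta[perm, ], herbs, paste0("L", 1:3)[perm])
  p <- list(herbs = c("B", "D"))
  expect_equal(as.numeric(scoreLabels(m1, p))[perm],
               as.numeric(scoreLabels(m2, p)), tolerance = 1e-9)
})

test_that("length normalization divides log-scores by the token count", {
  herbs <- c("A", "B", "C")
  beta <- rbind(c(.6, .3, .1), c(.2, .2, .6))
  m <- mockModel(beta, herbs, c("L1", "L2"))
  p <- list(herbs = c("A", "B", "C"))
  raw <- as.numeric(scoreLabels(m, p))
  norm <- as.numeric(scoreLabels(m, p, normalizeLength = TRUE))
  expect_equal(norm, raw / 3, tolerance = 1e-12)
  # normalization never changes the within-prescription ranking
  expect_equal(order(raw), order(norm))
})

test_that("a near-one-hot model predicts perfectly at a tiny threshold", {
  herbs <- c("A", "B", "C", "D")
  eps <- 1e-9
  beta <- rbind(c(.5 - eps, .5 - eps, eps, eps),
                c(eps, eps, .5 - eps, .5 - eps))
  m <- mockModel(beta, herbs, c("hot", "cold"))
  corp <- tinyCorpus(list(c("A", "B"), c("C", "D")),
                     labels = list("hot", "cold"))
  sw <- sweepThresholds(m, corp, grid = 1e-12)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$precision, 1)
  expect_equal(sw$recall, 1)
  expect_equal(sw$microF1, 1)
})

test_that("pair likelihood uses the joint count form at predict time", {
  corp <- tinyCorpus(
    list(c("A", "B", "C"), c("A", "B"), c("C", "D")),
    labels = list("L1", "L1", "L2"))
  nm <- herbNames(corp)
  pt <- new("PairTable",
            pairs = data.frame(herb_i = "A", herb_j = "B",
                               id_i = match("A", nm), id_j = match("B", nm),
                               support = .5, dependency = 2, cor = 1,
                               stringsAsFactors = FALSE),
            stoplist = character(),
            params = list(a = .5, b = .5, nTop = 1L, minCount = 0L))
  m <- fitLPH(corp, pt, lphConfig(nIterations = 20, seed = 1))
  sc <- scoreLabels(m, list(herbs = c("A", "B")))
  cts <- modelCounts(m)
  eta <- 0.1; V <- nHerbs(corp)
  idA <- match("A", nm); idB <- match("B", nm)
  manual <- log((cts$nkh[, idA] + eta) * (cts$nkh[, idB] + eta) /
                (cts$nk + eta * V))
  expect_equal(unname(as.numeric(sc)), unname(manual), tolerance = 1e-12)
  # beta-only model falls back to the product of member probabilities
  m2 <- m
  m2@counts <- list()
  expect_warning(sc2 <- scoreLabels(m2, list(herbs = c("A", "B"))),
                 "count arrays")
  expect_equal(unname(as.numeric(sc2)),
               unname(log(topicHerbMatrix(m)[, idA]) +
                      log(topicHerbMatrix(m)[, idB])), tolerance = 1e-12)
})

test_that("held-out prescriptions score their generating label on top", {
  g <- generateCorpus(generatorConfig(preset = "small", seed = 1))
  m <- fitLPH(g$corpus, plantedPairTable(g),
              lphConfig(nIterations = 200, seed = 1))
  cfgT <- generatorConfig(preset = "small", seed = 77)
  cfgT$N <- 80L; cfgT$labelCountProbs <- 1; cfgT$truthSimN <- 0L
  gt <- generateCorpus(cfgT)
  nm <- herbNames(gt$corpus)
  hits <- vapply(prescriptions(gt$corpus), function(p) {
    sc <- scoreLabels(m, list(herbs = nm[p$herbIds]))
    which.max(as.numeric(sc)) == p$labels[1]
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("threshold sweeps are reproducible row tables", {
  g <- generateCorpus(generatorConfig(preset = "small", seed = 2))
  m <- fitLPH(g$corpus, plantedPairTable(g),
              lphConfig(nIterations = 100, seed = 1))
  sub <- subsetCorpus(g$corpus, 1:40)
  grid <- 10^-(8:12)
  s1 <- sweepThresholds(m, sub, grid)
  s2 <- sweepThresholds(m, sub, grid)
  expect_identical(s1, s2)
  expect_equal(s1$T, grid)
})
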