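# Corpus used throughout: 3 labels, overlapping herb sets, one mined pair.
lphToyCorpus <- function() {
  tinyCorpus(
    list(c("A", "B", "C"), c("A", "B"), c("C", "D"), c("B", "C", "D")),
    labels = list(c("L1", "L2"), "L1", "L2", c("L2", "L3")))
}

lphToyPairs <- function(corpus) {
  # single mined rule (A, B) with nominal score
  nm <- herbNames(corpus)
  pairs <- data.frame(herb_i = "A", herb_j = "B",
                      id_i = match("A", nm), id_j = match("B", nm),
                      support = 0.5, dependency = 2, cor = 1.25,
                      stringsAsFactors = FALSE)
  new("PairTable", pairs = pairs, stoplist = character(),
      params = list(a = 0.5, b = 0.5, nTop = 1L, minCount = 0L))
}

test_that("greedy pair matching honors score order and exclusivity", {
  corp <- lphToyCorpus()
  p <- prescriptions(corp)[[1]]           # {A, B, C}
  pa <- assignPairs(p, lphToyPairs(corp))
  expect_equal(pa$x, c(1L, 1L, 0L))
  expect_equal(pa$partner, c(2L, 1L, NA))

  # empty table: degenerates to all singletons
  pa0 <- assignPairs(p, emptyPairTable())
  expect_equal(pa0$x, c(0L, 0L, 0L))

  # overlapping pairs: higher-cor pair consumes the shared herb
  nm <- herbNames(corp)
  two <- data.frame(herb_i = c("A", "B"), herb_j = c("B", "C"),
                    id_i = match(c("A", "B"), nm),
                    id_j = match(c("B", "C"), nm),
                    support = c(.5, .4), dependency = c(2, 1),
                    cor = c(2.0, 1.0), stringsAsFactors = FALSE)
  pt2 <- new("PairTable", pairs = two, stoplist = character(),
             params = list(a = .5, b = .5, nTop = 2L, minCount = 0L))
  pa2 <- assignPairs(p, pt2)
  expect_equal(pa2$x, c(1L, 1L, 0L))      # (A,B) won; C left unmatched
})

test_that("initialization is label-restricted, consistent and seeded", {
  corp <- lphToyCorpus()
  cfg <- lphConfig(nIterations = 1, seed = 9)
  st <- lphInitState(corp, lphToyPairs(corp), cfg)
  # forced assignment for single-label prescriptions
  lab <- match("L1", labelNames(corp))
  p2units <- which(st$units$pres == 2L)
  expect_true(all(st$z[p2units] == lab))
  # count identities
  expect_equal(rowSums(st$counts$nkh), st$counts$nk)
  expect_equal(rowSums(st$counts$npk), st$counts$np)
  expect_equal(sum(st$counts$nk), sum(lengths(lapply(
    prescriptions(corp), `[[`, "herbIds"))))
  # restriction to active labels
  for (u in seq_along(st$z))
    expect_true(st$z[u] %in% st$active[[st$units$pres[u]]])
  # determinism
  st2 <- lphInitState(corp, lphToyPairs(corp), cfg)
  expect_identical(st$z, st2$z)
})

test_that("prescriptions without labels are rejected for training", {
  corp <- makeCorpus(list(list(id = "p", herbs = c("A", "B"),
                               doses = c(1, 1), labels = character())))
  expect_error(fitLPH(corp, config = lphConfig(nIterations = 1)),
               "no labels")
})

test_that("a sweep preserves count identities and label restriction", {
  corp <- lphToyCorpus()
  st <- lphInitState(corp, lphToyPairs(corp), lphConfig(seed = 4))
  st <- lphGibbsSweep(st, 5)
  expect_equal(rowSums(st$counts$nkh), st$counts$nk)
  expect_equal(rowSums(st$counts$npk), st$counts$np)
  for (u in seq_along(st$z))
    expect_true(st$z[u] %in% st$active[[st$units$pres[u]]])
})

test_that("single-active-label corpora make sweeps a no-op on assignments", {
  corp <- tinyCorpus(list(c("A", "B"), c("C", "B")),
                     labels = list("only", "only"))
  st <- lphInitState(corp, emptyPairTable(), lphConfig(seed = 1))
  z0 <- st$z
  st <- lphGibbsSweep(st, 3)
  expect_identical(st$z, z0)
})

test_that("unit conditionals equal the hand-computed two-term product", {
  corp <- lphToyCorpus()
  cfg <- lphConfig(alpha = 2, eta = 0.1, seed = 7)
  st <- lphInitState(corp, lphToyPairs(corp), cfg)
  V <- st$V
  cts <- st$counts

  # singleton unit: herb C of prescription 1 (unit 2: pair then C)
  u <- 2L
  expect_true(is.na(st$units$h2[u]))
  h <- st$units$h1[u]; p <- st$units$pres[u]; kCur <- st$z[u]
  A <- st$active[[p]]
  nkh <- cts$nkh; nk <- cts$nk; npk <- cts$npk
  nkh[kCur, h] <- nkh[kCur, h] - 1; nk[kCur] <- nk[kCur] - 1
  npk[p, kCur] <- npk[p, kCur] - 1
  w <- sapply(A, function(k)
    (nkh[k, h] + 0.1) / (nk[k] + 0.1 * V) *
    (npk[p, k] + 2) / (cts$np[p] - 1 + 2 * length(A)))
  expect_equal(unname(as.numeric(lphUnitConditional(st, u))), w / sum(w),
               tolerance = 1e-12)

  # pair unit: (A, B) of prescription 1 shares one draw, joint numerator,
  # shared herb denominator applied once
  u <- 1L
  expect_false(is.na(st$units$h2[u]))
  hA <- st$units$h1[u]; hB <- st$units$h2[u]; kCur <- st$z[u]
  nkh <- cts$nkh; nk <- cts$nk; npk <- cts$npk
  nkh[kCur, hA] <- nkh[kCur, hA] - 1; nkh[kCur, hB] <- nkh[kCur, hB] - 1
  nk[kCur] <- nk[kCur] - 2; npk[p, kCur] <- npk[p, kCur] - 2
  w <- sapply(A, function(k)
    (nkh[k, hA] + 0.1) * (nkh[k, hB] + 0.1) / (nk[k] + 0.1 * V) *
    (npk[p, k] + 2) / (cts$np[p] - 2 + 2 * length(A)))
  expect_equal(unname(as.numeric(lphUnitConditional(st, u))), w / sum(w),
               tolerance = 1e-12)
})

test_that("the compiled sampler matches the pure-R reference trajectory", {
  corp <- lphToyCorpus()
  cfg <- lphConfig(nIterations = 10, seed = 21)
  m <- fitLPH(corp, lphToyPairs(corp), cfg)
  ref <- refGibbs(corp, lphToyPairs(corp), cfg, 10)
  expect_identical(modelCounts(m)$nkh, ref$nkh)
  expect_identical(modelCounts(m)$nk, ref$nk)
  expect_identical(modelCounts(m)$npk, ref$npk)
})

test_that("fits are deterministic and produce valid distributions", {
  corp <- lphToyCorpus()
  cfg <- lphConfig(nIterations = 30, seed = 2)
  m1 <- fitLPH(corp, lphToyPairs(corp), cfg)
  m2 <- fitLPH(corp, lphToyPairs(corp), cfg)
  expect_identical(modelCounts(m1), modelCounts(m2))
  expect_equal(unname(rowSums(topicHerbMatrix(m1))), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(functionMixtures(m1))), rep(1, 4),
               tolerance = 1e-12)
  # theta restricted to active labels
  th <- functionMixtures(m1)
  expect_equal(th[2, c("L2", "L3")], c(L2 = 0, L3 = 0))
})

test_that("zero pairs reduces LPH to Labeled LDA draw-for-draw", {
  corp <- lphToyCorpus()
  cfg <- lphConfig(nIterations = 40, seed = 13)
  a <- fitLPH(corp, emptyPairTable(), cfg)
  b <- fitLabeledLDA(corp, cfg)
  expect_identical(modelCounts(a), modelCounts(b))
  expect_identical(topicHerbMatrix(a), topicHerbMatrix(b))
})

test_that("single-label corpora admit the closed-form beta", {
  set.seed(3)
  herbs <- sprintf("h%02d", 1:8)
  corp <- makeCorpus(lapply(1:30, function(i) {
    n <- sample(2:5, 1)
    list(id = paste0("p", i), herbs = sample(herbs, n),
         doses = rep(1, n), labels = sample(c("u", "v"), 1))
  }))
  eta <- 0.1
  m <- fitLabeledLDA(corp, lphConfig(eta = eta, nIterations = 5, seed = 1))
  # with one active label per prescription, all its tokens are that label:
  # beta is a deterministic smoothed count ratio
  V <- nHerbs(corp)
  for (k in seq_len(nLabels(corp))) {
    cnt <- numeric(V)
    for (p in prescriptions(corp))
      if (p$labels[1] == k) cnt[p$herbIds] <- cnt[p$herbIds] + 1
    expect_equal(unname(topicHerbMatrix(m)[k, ]),
                 (cnt + eta) / (sum(cnt) + eta * V), tolerance = 1e-12)
  }
  # theta is one-hot
  th <- functionMixtures(m)
  expect_true(all(apply(th, 1, max) == 1))
})

test_that("beta recovery finds each label's generating herbs", {
  cfg <- generatorConfig(preset = "small", seed = 6)
  cfg$plantedPairs <- NULL
  cfg$truthSimN <- 0L
  g <- generateCorpus(cfg)
  m <- fitLabeledLDA(g$corpus, lphConfig(nIterations = 200, seed = 1))
  # top herbs under each fitted beta must be top herbs of the truth
  for (k in seq_len(5)) {
    topFit <- order(topicHerbMatrix(m)[k, ], decreasing = TRUE)[1:5]
    topTrue <- order(g$baseBeta[k, ], decreasing = TRUE)[1:10]
    expect_true(all(topFit %in% topTrue))
  }
})

test_that("averaged estimates are valid distributions too", {
  corp <- lphToyCorpus()
  m <- fitLPH(corp, lphToyPairs(corp),
              lphConfig(nIterations = 30, seed = 2,
                        estimateMode = "mean_last_S", S = 10))
  expect_equal(unname(rowSums(topicHerbMatrix(m))), rep(1, 3),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(functionMixtures(m))), rep(1, 4),
               tolerance = 1e-9)
})
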