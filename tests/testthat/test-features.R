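test_that("dosage standardization reproduces the worked formula values", {
  # the four-herb exterior-releasing formula, 2 d.p. as conventionally
  # tabulated
  expect_equal(round(standardizeDose(9, 2, 9), 2), 0.82)
  expect_equal(round(standardizeDose(6, 3, 9), 2), 0.50)
  expect_equal(round(standardizeDose(6, 4.5, 9), 2), 0.44)
  expect_equal(round(standardizeDose(3, 1.5, 9), 2), 0.29)
  # boundary and fallback behavior
  expect_equal(standardizeDose(11, 2, 9), 1.0)
  expect_warning(out <- standardizeDose(5, NA, NA), "missing")
  expect_equal(out, 1)
  expect_error(standardizeDose(-1, 2, 9))
})

test_that("standardization preserves dose order within a herb", {
  d <- sort(runif(20, 0.5, 40))
  expect_true(all(diff(standardizeDose(d, 3, 9)) > 0))
})

test_that("herb weights are the normalized standardized doses", {
  corp <- maHuangTangCorpus()
  p <- prescriptions(corp)[[1]]
  w <- herbWeights(p, herbTable(corp))
  dstar <- c(9 / 11, 6 / 12, 6 / 13.5, 3 / 10.5)
  expect_equal(w, dstar / sum(dstar), tolerance = 1e-12)
  expect_equal(sum(w), 1)
  # at 2 d.p. the tabulated weights give the textbook 0.4 for the monarch
  expect_equal(round(0.82 / (0.82 + 0.50 + 0.44 + 0.29), 1), 0.4)

  one <- tinyCorpus(list("A"), doses = list(4))
  expect_equal(suppressWarnings(
    herbWeights(prescriptions(one)[[1]], herbTable(one))), 1)

  eq <- makeCorpus(list(list(id = "e", herbs = c("X", "Y", "Z"),
                             doses = c(6, 6, 6), labels = "L")),
                   herbTable = data.frame(
                     name = c("X", "Y", "Z"), doseMin = 3, doseMax = 9,
                     natureFlavor = "", channelTropism = "",
                     efficiency = "", stringsAsFactors = FALSE))
  expect_equal(herbWeights(prescriptions(eq)[[1]], herbTable(eq)),
               rep(1 / 3, 3))
})

test_that("tfidf entries follow F(h) log(N/F') with edge cases", {
  corp <- tinyCorpus(
    list(c("A", "B"), c("A", "C"), c("A", "B", "C")),
    doses = list(c(2, 2), c(2, 2), c(2, 2, 2)))
  st <- tfidfStats(corp)
  expect_equal(st$docFreq, c(3L, 2L, 2L))
  v <- suppressWarnings(
    tfidfVector(prescriptions(corp)[[1]], herbTable(corp), st))
  # herb A is in every prescription: idf log(3/3) = 0
  expect_equal(v[["A"]], 0)
  expect_equal(v[["B"]], 0.5 * log(3 / 2), tolerance = 1e-12)
  expect_equal(v[["C"]], 0)  # absent herbs are exact zero

  # unseen-in-training herb gets F' = 1 with a warning
  st0 <- st; st0$docFreq[3] <- 0L
  expect_warning(v2 <- tfidfVector(prescriptions(corp)[[2]],
                                   herbTable(corp), st0), "unseen")
  expect_equal(v2[["C"]], 0.5 * log(3), tolerance = 1e-12)
})

test_that("tfidf matrix matches an independent brute-force recomputation", {
  set.seed(14)
  herbs <- sprintf("h%02d", 1:12)
  corp <- makeCorpus(lapply(1:20, function(i) {
    n <- sample(2:5, 1)
    list(id = paste0("p", i), herbs = sample(herbs, n),
         doses = runif(n, 1, 20), labels = "L")
  }), herbTable = data.frame(
    name = herbs, doseMin = 2, doseMax = 10,
    natureFlavor = "", channelTropism = "", efficiency = "",
    stringsAsFactors = FALSE))
  got <- featurizeCorpus(corp, "tfidf")$X
  ref <- bruteForceTfidf(corp)
  expect_equal(unname(got), unname(ref), tolerance = 1e-12)
  # row support equals the prescription's herb count (idf > 0 here)
  expect_equal(rowSums(got != 0),
               setNames(vapply(prescriptions(corp),
                               function(p) length(p$herbIds), 0),
                        rownames(got)))
})

test_that("the attribute vector encodes the top-two herbs' terms", {
  corp <- maHuangTangCorpus()
  v <- attributeVector(prescriptions(corp)[[1]], herbTable(corp))
  expect_length(v, 134L)
  expect_true(all(v %in% c(0, 0.5, 1)))
  # top herb by weight is Ephedrae Herba: spicy 1, slightly bitter 0.5,
  # warm 1, lungs 1, bladder 1
  expect_equal(v[["top1.spicy"]], 1)
  expect_equal(v[["top1.bitter"]], 0.5)
  expect_equal(v[["top1.warm"]], 1)
  expect_equal(v[["top1.lungs"]], 1)
  expect_equal(v[["top1.bladder"]], 1)
  expect_equal(v[["top1.cold"]], 0)
  # second by weight is Cinnamomi Ramulus
  expect_equal(v[["top2.sweet"]], 1)
  expect_equal(v[["top2.heart"]], 1)
})

test_that("single-herb prescriptions leave the second slot block empty", {
  corp <- makeCorpus(list(list(id = "s", herbs = "Ephedrae Herba",
                               doses = 6, labels = "L")),
                     herbTable = maHuangTangTable())
  v <- attributeVector(prescriptions(corp)[[1]], herbTable(corp))
  expect_true(all(v[68:134] == 0))
  expect_gt(sum(v[1:67]), 0)
})

test_that("attribute vectors ignore herb input order", {
  tab <- maHuangTangTable()
  fwd <- makeCorpus(list(list(
    id = "f", herbs = tab$name, doses = c(9, 6, 6, 3), labels = "L")),
    herbTable = tab)
  rev <- makeCorpus(list(list(
    id = "r", herbs = rev(tab$name), doses = rev(c(9, 6, 6, 3)),
    labels = "L")), herbTable = tab)
  expect_equal(
    attributeVector(prescriptions(fwd)[[1]], herbTable(fwd)),
    attributeVector(prescriptions(rev)[[1]], herbTable(rev)))
})

test_that("unknown attribute terms are ignored with a warning", {
  tab <- maHuangTangTable()
  tab$natureFlavor[1] <- "spicy;made-up-term"
  corp <- makeCorpus(list(list(id = "p", herbs = tab$name[1:2],
                               doses = c(9, 6), labels = "L")),
                     herbTable = tab)
  expect_warning(v <- attributeVector(prescriptions(corp)[[1]],
                                      herbTable(corp)), "made-up-term")
  expect_equal(v[["top1.spicy"]], 1)
})

test_that("feature matrix widths are V, 134 and V + 134", {
  g <- generateCorpus(generatorConfig(K = 4, V = 50, N = 40,
                                      truthSimN = 0, seed = 3))
  corp <- g$corpus
  expect_equal(ncol(featurizeCorpus(corp, "tfidf")$X), 50L)
  expect_equal(ncol(featurizeCorpus(corp, "attributes")$X), 134L)
  comb <- featurizeCorpus(corp, "combined")
  expect_equal(ncol(comb$X), 50L + 134L)
  expect_equal(dim(comb$Y), c(40L, 4L))
})
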