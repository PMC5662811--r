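# Classifier feature space: dosage-standardized TFIDF over the herb
# vocabulary, concatenated with a 134-dimensional herbal-attribute vector
# (the 9 + 12 + 46 = 67 attribute slots of each of the prescription's two
# highest-weight herbs).

#' Standardize a herb dosage by its usual range
#'
#' `d* = d / (d_max + d_min)`. Dimensionless, order-preserving within a
#' herb: a larger prescribed dose always maps to a larger `d*`. Herbs
#' without a recorded usual range fall back to `d* = 1` (standard weight)
#' with a warning.
#'
#' @param dose actual dose in grams (> 0)
#' @param doseMin,doseMax usual dosage range in grams
#' @return standardized dose (numeric)
#' @examples
#' standardizeDose(9, 2, 9)    # 0.8181...  (rounds to 0.82)
#' standardizeDose(3, 1.5, 9)  # 0.2857...  (rounds to 0.29)
#' @export
standardizeDose <- function(dose, doseMin, doseMax) {
  stopifnot(all(dose > 0))
  out <- dose / (doseMax + doseMin)
  missing <- is.na(doseMin) | is.na(doseMax)
  if (any(missing)) {
    warning("missing usual dosage range; standardized dose set to 1")
    out[missing] <- 1
  }
  out
}

# Standardized doses for one prescription against the corpus herb table.
.presStdDoses <- function(prescription, herbs) {
  dmin <- herbs$doseMin[prescription$herbIds]
  dmax <- herbs$doseMax[prescription$herbIds]
  suppressWarnings(standardizeDose(prescription$doses, dmin, dmax))
}

#' Within-prescription herb weights
#'
#' Dosage-derived term frequency: `F(h_i) = d_i* / sum_j d_j*` over the
#' prescription, so the weights sum to 1.
#'
#' @param prescription a prescription record
#' @param herbs the herb metadata data.frame ([herbTable()])
#' @return numeric vector parallel to the prescription's herbs
#' @export
herbWeights <- function(prescription, herbs) {
  d <- .presStdDoses(prescription, herbs)
  d / sum(d)
}

#' Document-frequency statistics of a training corpus
#'
#' `N` (number of prescriptions) and `F'(h)` (number of prescriptions
#' containing each herb), the inputs of the IDF term. Compute on the
#' training fold only and reuse for the fold's test split.
#'
#' @param corpus a [HerbCorpus-class]
#' @return list with `N`, `docFreq` (length-V integer), `logBase`
#' @param logBase base of the IDF logarithm (default natural)
#' @export
tfidfStats <- function(corpus, logBase = exp(1)) {
  V <- nHerbs(corpus)
  df <- integer(V)
  for (p in corpus@prescriptions) df[p$herbIds] <- df[p$herbIds] + 1L
  list(N = nPrescriptions(corpus), docFreq = df, logBase = logBase)
}

#' TFIDF vector of one prescription
#'
#' `t_h = F(h) * log(N / F'(h))` for herbs present in the prescription,
#' 0 elsewhere. A herb unseen in the training statistics gets
#' `F'(h) = 1` (maximal IDF) with a warning.
#'
#' @param prescription a prescription record
#' @param herbs herb metadata data.frame
#' @param stats training statistics from [tfidfStats()]
#' @return numeric length-V vector named by herb
#' @export
tfidfVector <- function(prescription, herbs, stats) {
  V <- nrow(herbs)
  out <- setNames(numeric(V), herbs$name)
  Fw <- herbWeights(prescription, herbs)
  df <- stats$docFreq[prescription$herbIds]
  if (any(df == 0)) {
    warning("herb unseen in training statistics; using F'=1")
    df[df == 0] <- 1L
  }
  out[prescription$herbIds] <- Fw * log(stats$N / df, base = stats$logBase)
  out
}

#' Attribute term vocabulary
#'
#' Loads the three attribute term lists (9 nature & flavor, 12 channel
#' tropism, 46 efficiency terms) that define the 67 attribute slots per
#' herb. The packaged defaults are standard TCM term sets; pass file
#' paths to substitute your own.
#'
#' @param natureFlavorFile,channelTropismFile,efficiencyFile optional
#'   plain-text files, one term per line; defaults ship in
#'   `inst/extdata/`.
#' @return list of class `"attributeVocabulary"` with components
#'   `natureFlavor`, `channelTropism`, `efficiency` and a `slots`
#'   character vector of length 67
#' @export
attributeVocabulary <- function(natureFlavorFile = NULL,
                                channelTropismFile = NULL,
                                efficiencyFile = NULL) {
  rd <- function(file, default) {
    if (is.null(file))
      file <- system.file("extdata", default, package = "HerbTopics")
    x <- readLines(file, warn = FALSE)
    x[nzchar(x)]
  }
  nf <- rd(natureFlavorFile, "nature_flavor.txt")
  ct <- rd(channelTropismFile, "channel_tropism.txt")
  ef <- rd(efficiencyFile, "efficiency.txt")
  structure(list(natureFlavor = nf, channelTropism = ct,
                 efficiency = ef,
                 slots = c(nf, ct, ef)),
            class = "attributeVocabulary")
}

# 67-slot attribute profile of one herb row; weights 1 / 0.5 ("slightly")
.herbAttributeSlots <- function(herbRow, vocab) {
  out <- setNames(numeric(length(vocab$slots)), vocab$slots)
  fill <- function(terms, allowed) {
    w <- parseAttributeTerms(terms)
    unknown <- setdiff(names(w), allowed)
    if (length(unknown))
      warning("unknown attribute term(s) ignored: ",
              paste(unknown, collapse = ", "))
    w[names(w) %in% allowed]
  }
  w <- c(fill(herbRow$natureFlavor, vocab$natureFlavor),
         fill(herbRow$channelTropism, vocab$channelTropism),
         fill(herbRow$efficiency, vocab$efficiency))
  out[names(w)] <- w
  out
}

#' Attribute feature vector of a prescription
#'
#' The prescription's two highest-weight herbs (by `F(h)`; ties broken by
#' larger standardized dose, then lexicographic name) each contribute
#' their 67 attribute slots (entries 1, or 0.5 for `"slightly"` terms),
#' concatenated into a 134-dimensional vector. A single-herb prescription
#' leaves the second 67 slots at zero. Selection depends only on the
#' weights, not on input order.
#'
#' @param prescription a prescription record
#' @param herbs herb metadata data.frame
#' @param vocab an [attributeVocabulary()]
#' @return numeric vector of length 134 with entries in {0, 0.5, 1}
#' @export
attributeVector <- function(prescription, herbs,
                            vocab = attributeVocabulary()) {
  Fw <- herbWeights(prescription, herbs)
  d <- .presStdDoses(prescription, herbs)
  nm <- herbs$name[prescription$herbIds]
  ord <- order(-Fw, -d, nm)
  top <- ord[seq_len(min(2L, length(ord)))]
  out <- numeric(2L * length(vocab$slots))
  names(out) <- c(paste0("top1.", vocab$slots), paste0("top2.", vocab$slots))
  for (i in seq_along(top)) {
    row <- herbs[prescription$herbIds[top[i]], , drop = FALSE]
    out[((i - 1L) * length(vocab$slots)) + seq_along(vocab$slots)] <-
      .herbAttributeSlots(row, vocab)
  }
  out
}

#' Build the feature matrix of a corpus
#'
#' @param corpus a [HerbCorpus-class]
#' @param mode `"tfidf"` (width V), `"attributes"` (width 134) or
#'   `"combined"` (width V + 134)
#' @param stats training-fold statistics from [tfidfStats()]; computed on
#'   `corpus` itself when omitted (fine for training data, leaky for test
#'   data — pass the training fold's stats there)
#' @param vocab an [attributeVocabulary()]
#' @return list with `X` (N x width feature matrix) and `Y` (N x K binary
#'   label matrix from [labelMatrix()])
#' @export
featurizeCorpus <- function(corpus, mode = c("combined", "tfidf",
                                             "attributes"),
                            stats = NULL, vocab = attributeVocabulary()) {
  mode <- match.arg(mode)
  if (is.null(stats)) stats <- tfidfStats(corpus)
  h <- herbTable(corpus)
  rows <- lapply(corpus@prescriptions, function(p) {
    parts <- list()
    if (mode %in% c("combined", "tfidf"))
      parts$tfidf <- tfidfVector(p, h, stats)
    if (mode %in% c("combined", "attributes"))
      parts$attr <- attributeVector(p, h, vocab)
    unlist(parts, use.names = FALSE)
  })
  X <- do.call(rbind, rows)
  colnames(X) <- c(
    if (mode %in% c("combined", "tfidf")) paste0("tfidf.", h$name),
    if (mode %in% c("combined", "attributes"))
      c(paste0("top1.", vocab$slots), paste0("top2.", vocab$slots)))
  rownames(X) <- vapply(corpus@prescriptions, `[[`, "", "id")
  list(X = X, Y = labelMatrix(corpus))
}
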