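#' @import methods
#' @importFrom stats rbeta rbinom rgamma rlnorm rmultinom runif setNames
#'   predict chisq.test
#' @importFrom utils read.delim write.table head
#' @useDynLib HerbTopics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' HerbCorpus: a corpus of prescriptions with herb metadata
#'
#' A prescription (formula) corpus in the bag-of-herbs representation: each
#' prescription is a set of (herb, dosage in grams) entries plus a set of
#' function labels drawn from a fixed K-label vocabulary. Herb metadata
#' (usual dosage range and attribute terms) lives in the `herbs` table.
#'
#' @slot prescriptions list; each element is a list with components
#'   `id` (character scalar), `herbIds` (integer, 1-based indices into the
#'   herb table), `doses` (numeric, grams, parallel to `herbIds`) and
#'   `labels` (integer, 1-based indices into `labelNames`; may be empty for
#'   unlabeled test records).
#' @slot herbs data.frame with one row per herb: `name` (character, unique),
#'   `doseMin`, `doseMax` (numeric grams, NA when the usual range is
#'   unknown), `natureFlavor`, `channelTropism`, `efficiency` (character,
#'   `;`-separated attribute terms; a `"slightly "` prefix encodes term
#'   weight 0.5, all other terms weigh 1.0). Row i is the herb with id i.
#' @slot labelNames character vector of the K function-label names.
#'
#' @seealso [readCorpus()], [writeCorpus()], [generateCorpus()]
#' @export
setClass("HerbCorpus",
  representation(
    prescriptions = "list",
    herbs = "data.frame",
    labelNames = "character"
  )
)

setValidity("HerbCorpus", function(object) {
  msgs <- character()
  h <- object@herbs
  required <- c("name", "doseMin", "doseMax",
                "natureFlavor", "channelTropism", "efficiency")
  if (!all(required %in% names(h)))
    return(paste("herbs table must have columns:",
                 paste(required, collapse = ", ")))
  if (anyDuplicated(h$name))
    msgs <- c(msgs, "duplicate herb names in herb table")
  bad <- !is.na(h$doseMin) & !is.na(h$doseMax) & h$doseMin > h$doseMax
  if (any(bad))
    msgs <- c(msgs, paste0("doseMin > doseMax for herb(s): ",
                           paste(h$name[bad], collapse = ", ")))
  V <- nrow(h)
  K <- length(object@labelNames)
  for (p in object@prescriptions) {
    if (!all(c("id", "herbIds", "doses", "labels") %in% names(p))) {
      msgs <- c(msgs, "prescription missing a required component")
      break
    }
    if (length(p$herbIds) < 1)
      msgs <- c(msgs, paste0("prescription '", p$id, "' has no herbs"))
    if (anyDuplicated(p$herbIds))
      msgs <- c(msgs, paste0("duplicate herb in prescription '", p$id, "'"))
    if (length(p$herbIds) && (min(p$herbIds) < 1 || max(p$herbIds) > V))
      msgs <- c(msgs, paste0("herb id out of range in prescription '",
                             p$id, "'"))
    if (length(p$doses) != length(p$herbIds))
      msgs <- c(msgs, paste0("dose/herb length mismatch in '", p$id, "'"))
    if (length(p$doses) && any(p$doses <= 0))
      msgs <- c(msgs, paste0("non-positive dose in prescription '",
                             p$id, "'"))
    if (length(p$labels) && (min(p$labels) < 1 || max(p$labels) > K))
      msgs <- c(msgs, paste0("label index out of range in '", p$id, "'"))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' PairTable: ranked herb-pair compatibility rules
#'
#' Holds herb pairs scored by the combined co-occurrence score
#' `cor = a * support + b * dependency`, where `support` is the joint
#' probability that the two herbs occur in the same prescription and
#' `dependency` is the lift-like ratio of the joint to the product of the
#' marginals. Pairs are sorted by `cor` descending with the deterministic
#' tie-break (support descending, then lexicographic herb names).
#'
#' @slot pairs data.frame with columns `herb_i`, `herb_j` (character names,
#'   ordered so the herb with smaller id comes first), `id_i`, `id_j`
#'   (integer herb ids), `support`, `dependency`, `cor` (numeric).
#' @slot stoplist character; herb names excluded from mining.
#' @slot params list with elements `a`, `b`, `nTop`, `minCount`.
#'
#' @seealso [minePairs()], [topNPairs()]
#' @export
setClass("PairTable",
  representation(
    pairs = "data.frame",
    stoplist = "character",
    params = "list"
  )
)

setValidity("PairTable", function(object) {
  p <- object@pairs
  need <- c("herb_i", "herb_j", "id_i", "id_j",
            "support", "dependency", "cor")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (nrow(p)) {
    if (any(p$id_i >= p$id_j))
      return("pairs must be ordered with id_i < id_j")
    if (any(p$support < 0 | p$support > 1))
      return("support must lie in [0, 1]")
    if (any(p$dependency < 0))
      return("dependency must be nonnegative")
    if (any(p$herb_i %in% object@stoplist | p$herb_j %in% object@stoplist))
      return("pair table contains a stoplist herb")
  }
  TRUE
})

#' LPHModel: a fitted pair-aware supervised topic model
#'
#' The result of collapsed Gibbs training of the Label-Prescription-Herb
#' model (or its Labeled-LDA special case when the pair table is empty):
#' per-function herb multinomials `beta`, per-prescription function
#' mixtures `theta`, and the final count state needed to evaluate pair
#' likelihoods at prediction time.
#'
#' @slot beta K x V matrix; row k is the multinomial over herbs for
#'   function label k (rows sum to 1).
#' @slot theta N x K matrix; row p is the function mixture of training
#'   prescription p, zero outside its active label set.
#' @slot counts list with final-state count arrays `nkh` (K x V), `nk`
#'   (length K), `npk` (N x K), `np` (length N).
#' @slot config list of fitting hyperparameters (see [lphConfig()]).
#' @slot labelNames character, length K.
#' @slot herbNames character, length V.
#' @slot pairTable the [PairTable-class] used during fitting (may hold zero
#'   pairs, in which case the model is exactly Labeled LDA).
#' @slot pairTrace integer matrix (sweeps x pair-units) of the label
#'   assigned to each herb-pair unit during the recorded final sweeps;
#'   0 x 0 when no pairs or no trace was requested. Column names identify
#'   the pair unit as "<prescription id>:<herb_i>+<herb_j>".
#'
#' @seealso [fitLPH()], [fitLabeledLDA()], [scoreLabels()]
#' @export
setClass("LPHModel",
  representation(
    beta = "matrix",
    theta = "matrix",
    counts = "list",
    config = "list",
    labelNames = "character",
    herbNames = "character",
    pairTable = "PairTable",
    pairTrace = "matrix"
  )
)

setValidity("LPHModel", function(object) {
  K <- length(object@labelNames)
  V <- length(object@herbNames)
  if (!all(dim(object@beta) == c(K, V)))
    return("beta must be K x V")
  if (ncol(object@theta) != K)
    return("theta must have K columns")
  if (any(abs(rowSums(object@beta) - 1) > 1e-9))
    return("beta rows must sum to 1")
  th <- rowSums(object@theta)
  if (nrow(object@theta) && any(abs(th - 1) > 1e-9))
    return("theta rows must sum to 1")
  TRUE
})

# ---- accessors ----------------------------------------------------------

#' Corpus accessors
#'
#' @param x a [HerbCorpus-class]
#' @return `nPrescriptions`, `nHerbs`, `nLabels` return integer counts;
#'   `herbNames` and `labelNames` character vectors; `prescriptions` the
#'   list of prescription records; `herbTable` the herb metadata
#'   data.frame.
#' @name corpus-accessors
#' @aliases nPrescriptions nHerbs nLabels herbNames labelNames
#'   prescriptions herbTable
NULL

#' @rdname corpus-accessors
#' @export
nPrescriptions <- function(x) length(x@prescriptions)

#' @rdname corpus-accessors
#' @export
nHerbs <- function(x) nrow(x@herbs)

#' @rdname corpus-accessors
#' @export
nLabels <- function(x) length(x@labelNames)

#' @rdname corpus-accessors
#' @export
herbNames <- function(x) x@herbs$name

#' @rdname corpus-accessors
#' @export
labelNames <- function(x) {
  if (is(x, "LPHModel")) x@labelNames else x@labelNames
}

#' @rdname corpus-accessors
#' @export
prescriptions <- function(x) x@prescriptions

#' @rdname corpus-accessors
#' @export
herbTable <- function(x) x@herbs

#' Pair table accessors
#'
#' @param x a [PairTable-class]
#' @return `pairs` returns the scored pair data.frame; `stoplist` the
#'   excluded herb names; `nPairs` the number of pairs.
#' @name pairtable-accessors
#' @aliases pairs stoplist nPairs
NULL

#' @rdname pairtable-accessors
#' @export
pairRules <- function(x) x@pairs

#' @rdname pairtable-accessors
#' @export
stoplist <- function(x) x@stoplist

#' @rdname pairtable-accessors
#' @export
nPairs <- function(x) nrow(x@pairs)

#' Model accessors
#'
#' @param x a [LPHModel-class]
#' @return `topicHerbMatrix` returns the K x V `beta` matrix;
#'   `functionMixtures` the N x K `theta` matrix; `modelCounts` the final
#'   Gibbs count state.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
topicHerbMatrix <- function(x) x@beta

#' @rdname model-accessors
#' @export
functionMixtures <- function(x) x@theta

#' @rdname model-accessors
#' @export
modelCounts <- function(x) x@counts

# ---- show methods -------------------------------------------------------

setMethod("show", "HerbCorpus", function(object) {
  cat("HerbCorpus with", nPrescriptions(object), "prescriptions,",
      nHerbs(object), "herbs,", nLabels(object), "function labels\n")
  n <- min(3L, nPrescriptions(object))
  for (i in seq_len(n)) {
    p <- object@prescriptions[[i]]
    cat("  ", p$id, ": ", length(p$herbIds), " herbs, labels {",
        paste(object@labelNames[p$labels], collapse = ", "), "}\n",
        sep = "")
  }
  if (nPrescriptions(object) > n) cat("  ...\n")
})

setMethod("show", "PairTable", function(object) {
  cat("PairTable with", nPairs(object), "herb pairs (a =",
      object@params$a, ", b =", object@params$b, ")\n")
  if (length(object@stoplist))
    cat("  stoplist:", paste(object@stoplist, collapse = ", "), "\n")
  if (nPairs(object)) {
    top <- head(object@pairs, 3L)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %s + %s  cor = %.4g\n",
                  top$herb_i[i], top$herb_j[i], top$cor[i]))
    if (nPairs(object) > 3L) cat("  ...\n")
  }
})

setMethod("show", "LPHModel", function(object) {
  K <- length(object@labelNames)
  cat("LPHModel:", K, "function labels x", length(object@herbNames),
      "herbs;", nrow(object@theta), "training prescriptions\n")
  cat("  pairs used:", nPairs(object@pairTable),
      if (nPairs(object@pairTable) == 0) "(Labeled LDA)" else "", "\n")
  cat("  alpha =", object@config$alpha, " eta =", object@config$eta,
      " sweeps =", object@config$nIterations, "\n")
})
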