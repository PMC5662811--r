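# Herb-pair compatibility mining from prescription co-occurrence.
#
# For herbs h_i, h_j:
#   support    = p(h_i, h_j)                    joint occurrence frequency
#   dependency = p(h_i, h_j) / (p(h_i) p(h_j))  lift-like dependency ratio
#   cor        = a * support + b * dependency
# Probabilities are prescription-level presence/absence frequencies
# (a pair counts once per prescription, regardless of dosage).

#' Count prescription-level herb co-occurrence
#'
#' @param corpus a [HerbCorpus-class]
#' @return list with `pairCounts` (data.frame `id_i`, `id_j`, `count` for
#'   every unordered pair co-occurring in at least one prescription, with
#'   `id_i < id_j`), `marginals` (integer vector, length V: number of
#'   prescriptions containing each herb) and `N` (corpus size). Pairs that
#'   never co-occur are absent (implicit support 0).
#' @export
countCooccurrence <- function(corpus) {
  N <- nPrescriptions(corpus)
  if (N == 0) stop("corpus is empty")
  V <- nHerbs(corpus)
  marginals <- integer(V)
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (p in corpus@prescriptions) {
    ids <- sort(p$herbIds)
    marginals[ids] <- marginals[ids] + 1L
    n <- length(ids)
    if (n < 2) next
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      key <- paste0(ids[a], "_", ids[b])
      env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
    }
  }
  keys <- ls(env)
  if (length(keys)) {
    ij <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
    pc <- data.frame(id_i = as.integer(ij[, 1]),
                     id_j = as.integer(ij[, 2]),
                     count = vapply(keys, function(k) env[[k]], 0L,
                                    USE.NAMES = FALSE))
    pc <- pc[order(pc$id_i, pc$id_j), , drop = FALSE]
    rownames(pc) <- NULL
  } else {
    pc <- data.frame(id_i = integer(), id_j = integer(), count = integer())
  }
  list(pairCounts = pc, marginals = marginals, N = N,
       herbNames = herbNames(corpus))
}

#' Score co-occurring herb pairs
#'
#' Computes support, dependency and the combined score
#' `cor = a * support + b * dependency` for every counted pair, dropping
#' pairs that touch the stoplist (by default Glycyrrhizae Radix, the
#' universal harmonizer whose ubiquity makes its pairings uninformative)
#' and pairs co-occurring fewer than `minCount` times (a rare pair seen
#' once has an N-inflated dependency; 0 disables the floor).
#'
#' @param counts output of [countCooccurrence()]
#' @param a,b nonnegative weights of support and dependency (default 0.5
#'   each)
#' @param stoplist character vector of herb names excluded from mining
#' @param minCount minimum co-occurrence count (default 2)
#' @return a [PairTable-class] sorted by `cor` descending (ties: support
#'   descending, then lexicographic herb names)
#' @export
scorePairs <- function(counts, a = 0.5, b = 0.5,
                       stoplist = "Glycyrrhizae Radix", minCount = 2L) {
  stopifnot(a >= 0, b >= 0)
  pc <- counts$pairCounts
  N <- counts$N
  nm <- counts$herbNames
  stopIds <- which(nm %in% stoplist)
  keep <- pc$count >= minCount &
    !(pc$id_i %in% stopIds) & !(pc$id_j %in% stopIds) &
    counts$marginals[pc$id_i] > 0 & counts$marginals[pc$id_j] > 0
  pc <- pc[keep, , drop = FALSE]
  support <- pc$count / N
  pI <- counts$marginals[pc$id_i] / N
  pJ <- counts$marginals[pc$id_j] / N
  dependency <- support / (pI * pJ)
  df <- data.frame(herb_i = nm[pc$id_i], herb_j = nm[pc$id_j],
                   id_i = pc$id_i, id_j = pc$id_j,
                   support = support, dependency = dependency,
                   cor = a * support + b * dependency,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$cor, -df$support, df$herb_i, df$herb_j), ,
           drop = FALSE]
  rownames(df) <- NULL
  new("PairTable", pairs = df, stoplist = as.character(stoplist),
      params = list(a = a, b = b, nTop = NA_integer_,
                    minCount = as.integer(minCount)))
}

#' Keep the top-N pairs by combined score
#'
#' @param pairTable a [PairTable-class] (already sorted by `cor`)
#' @param nTop number of pairs to return; if fewer pairs are available all
#'   are returned with a warning
#' @return a [PairTable-class] with at most `nTop` pairs
#' @export
topNPairs <- function(pairTable, nTop) {
  stopifnot(nTop >= 1)
  p <- pairTable@pairs
  if (nTop > nrow(p)) {
    warning("requested ", nTop, " pairs but only ", nrow(p),
            " are available; returning all")
    nTop <- nrow(p)
  }
  out <- pairTable
  out@pairs <- p[seq_len(nTop), , drop = FALSE]
  out@params$nTop <- as.integer(nTop)
  out
}

#' Mine ranked herb pairs from a corpus
#'
#' Convenience pipeline: [countCooccurrence()], [scorePairs()],
#' [topNPairs()].
#'
#' @inheritParams scorePairs
#' @param corpus a [HerbCorpus-class]
#' @param nTop number of top-ranked pairs to keep (default all)
#' @return a [PairTable-class]
#' @export
minePairs <- function(corpus, a = 0.5, b = 0.5,
                      stoplist = "Glycyrrhizae Radix",
                      minCount = 2L, nTop = Inf) {
  pt <- scorePairs(countCooccurrence(corpus), a = a, b = b,
                   stoplist = stoplist, minCount = minCount)
  if (is.finite(nTop) && nrow(pt@pairs) > nTop) pt <- topNPairs(pt, nTop)
  pt
}

#' An empty pair table
#'
#' With zero pairs the topic model degenerates exactly to Labeled LDA.
#'
#' @return a [PairTable-class] holding no pairs
#' @export
emptyPairTable <- function() {
  new("PairTable",
      pairs = data.frame(herb_i = character(), herb_j = character(),
                         id_i = integer(), id_j = integer(),
                         support = numeric(), dependency = numeric(),
                         cor = numeric(), stringsAsFactors = FALSE),
      stoplist = character(),
      params = list(a = NA_real_, b = NA_real_, nTop = 0L, minCount = 0L))
}

#' Precision at N of a mined pair ranking
#'
#' The fraction of the top-`n` ranked pairs that appear in a gold set of
#' accepted pairs (order within a pair is ignored).
#'
#' @param pairTable a [PairTable-class]
#' @param goldPairs data.frame or 2-column matrix of herb-name pairs, or a
#'   character vector of `"name1|name2"` keys
#' @param n how many top pairs to assess; must not exceed the table size
#' @return ratio in `[0, 1]`
#' @export
precisionAtN <- function(pairTable, goldPairs, n) {
  if (n <= 0) stop("n must be positive")
  p <- pairTable@pairs
  if (n > nrow(p)) stop("n exceeds the number of mined pairs")
  goldKeys <- .pairKeys(goldPairs)
  top <- p[seq_len(n), , drop = FALSE]
  keys <- .pairKeys(cbind(top$herb_i, top$herb_j))
  sum(keys %in% goldKeys) / n
}

.pairKeys <- function(x) {
  if (is.character(x) && is.null(dim(x))) return(unique(x))
  x <- as.matrix(x)
  if (nrow(x) == 0) return(character())
  apply(x, 1, function(r) paste(sort(c(r[[1]], r[[2]])), collapse = "|"))
}

#' Export / re-import a pair table as an edge list
#'
#' Writes a TSV edge list (`herb_i`, `herb_j`, `support`, `dependency`,
#' `cor`) suitable for graph tools; `readPairGraph` reconstructs a
#' [PairTable-class] from it (herb ids are re-derived from the name order
#' of the supplied corpus when given, else assigned by first appearance).
#'
#' @param pairTable a [PairTable-class]
#' @param path output TSV path
#' @return `path` invisibly
#' @export
exportPairGraph <- function(pairTable, path) {
  p <- pairTable@pairs
  out <- p[, c("herb_i", "herb_j", "support", "dependency", "cor")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exportPairGraph
#' @param corpus optional [HerbCorpus-class] providing the herb-id mapping
#' @export
readPairGraph <- function(path, corpus = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  nm <- if (!is.null(corpus)) herbNames(corpus) else
    unique(c(rbind(df$herb_i, df$herb_j)))
  idI <- match(df$herb_i, nm)
  idJ <- match(df$herb_j, nm)
  if (anyNA(idI) || anyNA(idJ))
    stop("edge list names a herb absent from the corpus")
  flip <- idI > idJ
  pairs <- data.frame(
    herb_i = ifelse(flip, df$herb_j, df$herb_i),
    herb_j = ifelse(flip, df$herb_i, df$herb_j),
    id_i = pmin(idI, idJ), id_j = pmax(idI, idJ),
    support = df$support, dependency = df$dependency, cor = df$cor,
    stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$cor, -pairs$support,
                       pairs$herb_i, pairs$herb_j), , drop = FALSE]
  rownames(pairs) <- NULL
  new("PairTable", pairs = pairs, stoplist = character(),
      params = list(a = NA_real_, b = NA_real_,
                    nTop = nrow(pairs), minCount = 0L))
}
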