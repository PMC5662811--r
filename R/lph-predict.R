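# Multilabel function prediction from a fitted model: per-label
# log-scores of the raw (unnormalized) likelihood product, thresholded at
# a user-chosen T. The label prior p(k) is treated as constant, so scores
# are exact proportionality — no renormalization — because the threshold
# is meant to act on the raw product.

#' Score function labels for a prescription
#'
#' Detects mined pairs inside the prescription via [assignPairs()], then
#' for every label k accumulates
#' `log p(H | k) = sum over singleton herbs log beta[k, h] +
#'  sum over pairs log betaPair[k, (h_i, h_j)]`,
#' where the pair likelihood is evaluated from the stored count arrays as
#' `(n_kh[h_i] + eta)(n_kh[h_j] + eta) / (n_k + eta * V)` — the joint
#' numerator form with the shared denominator applied once. If the model
#' carries no counts (beta-only artifact) the pair term falls back to
#' `beta[k, h_i] * beta[k, h_j]` with a warning.
#'
#' @param model an [LPHModel-class]
#' @param prescription a prescription record (list with `herbIds` indexing
#'   the model's herb vocabulary, or `herbs` as character names)
#' @param pairTable optional [PairTable-class]; defaults to the table the
#'   model was fitted with
#' @param normalizeLength if `TRUE`, divide each log-score by the token
#'   count (geometric-mean scoring); off by default since the raw product
#'   is what the threshold is calibrated against
#' @return object of class `"labelScores"`: named numeric vector of
#'   per-label log-scores with attributes `nTokens` and `labelNames`
#' @export
scoreLabels <- function(model, prescription, pairTable = NULL,
                        normalizeLength = FALSE) {
  if (is.null(pairTable)) pairTable <- model@pairTable
  if (!is.null(prescription$herbs) && is.null(prescription$herbIds))
    prescription$herbIds <- match(prescription$herbs, model@herbNames)
  ids <- prescription$herbIds
  known <- !is.na(ids) & ids >= 1 & ids <= length(model@herbNames)
  if (!any(known)) stop("no prescription herb is in the model vocabulary")
  if (any(!known))
    warning(sum(!known), " unknown herb(s) skipped at predict time")
  prescription$herbIds <- ids <- ids[known]

  K <- length(model@labelNames)
  eta <- model@config$eta
  V <- length(model@herbNames)
  haveCounts <- length(model@counts) > 0 && !is.null(model@counts$nkh)

  pa <- assignPairs(prescription, pairTable)
  scores <- numeric(K)
  nTokens <- length(ids)
  done <- rep(FALSE, length(ids))
  for (i in seq_along(ids)) {
    if (done[i]) next
    if (pa$x[i] == 1L) {
      j <- pa$partner[i]
      done[j] <- TRUE
      if (haveCounts) {
        num <- (model@counts$nkh[, ids[i]] + eta) *
          (model@counts$nkh[, ids[j]] + eta)
        scores <- scores + log(num / (model@counts$nk + eta * V))
      } else {
        warning("model carries no count arrays; pair likelihood ",
                "falls back to the product of member probabilities")
        scores <- scores + log(model@beta[, ids[i]]) +
          log(model@beta[, ids[j]])
      }
    } else {
      scores <- scores + log(model@beta[, ids[i]])
    }
  }
  if (normalizeLength) scores <- scores / nTokens
  structure(setNames(scores, model@labelNames),
            nTokens = nTokens, class = "labelScores")
}

#' Threshold label scores into a predicted label set
#'
#' Returns the labels whose raw likelihood product exceeds `T`, i.e.
#' `{k : exp(score_k) > T}`. The predicted set shrinks monotonically as
#' `T` grows; an empty set is permitted.
#'
#' @param scores a `"labelScores"` vector from [scoreLabels()]
#' @param T positive threshold on the probability scale (e.g. `1e-8`)
#' @return character vector of predicted label names
#' @export
predictLabels <- function(scores, T) {
  stopifnot(T > 0)
  names(scores)[as.numeric(scores) > log(T)]
}

#' Predict label sets for a whole corpus
#'
#' @param model an [LPHModel-class]
#' @param corpus a [HerbCorpus-class] of test prescriptions
#' @param T threshold (see [predictLabels()])
#' @param pairTable optional [PairTable-class] override
#' @return list (one element per prescription) of predicted label-name
#'   vectors; attribute `"scores"` holds the N x K log-score matrix
#' @export
predictCorpus <- function(model, corpus, T = 1e-8, pairTable = NULL) {
  sc <- t(vapply(corpus@prescriptions, function(p)
    as.numeric(scoreLabels(model, p, pairTable)),
    numeric(length(model@labelNames))))
  colnames(sc) <- model@labelNames
  preds <- lapply(seq_len(nrow(sc)), function(i)
    model@labelNames[sc[i, ] > log(T)])
  attr(preds, "scores") <- sc
  preds
}

#' Evaluate a model across a threshold grid
#'
#' One evaluation row per threshold: micro-averaged Precision, Recall and
#' Micro-F1 of the thresholded predictions against the test corpus's true
#' label sets.
#'
#' @param model an [LPHModel-class]
#' @param corpus a labeled test [HerbCorpus-class]
#' @param grid numeric vector of thresholds
#' @param pairTable optional [PairTable-class] override
#' @return data.frame with columns `T`, `precision`, `recall`, `microF1`
#' @export
sweepThresholds <- function(model, corpus, grid = 10^-(5:9),
                            pairTable = NULL) {
  preds <- predictCorpus(model, corpus, T = grid[1],
                         pairTable = pairTable)
  sc <- attr(preds, "scores")
  truth <- lapply(corpus@prescriptions, function(p)
    corpus@labelNames[p$labels])
  rows <- lapply(grid, function(Tv) {
    pr <- lapply(seq_len(nrow(sc)), function(i)
      model@labelNames[sc[i, ] > log(Tv)])
    ev <- evaluateLabels(pr, truth)
    data.frame(T = Tv, precision = ev$precision, recall = ev$recall,
               microF1 = ev$microF1)
  })
  do.call(rbind, rows)
}
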