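# One-vs-rest multilabel classifiers over the feature space and the
# shared micro-averaged evaluation (Precision, Recall, Micro-F1) with
# repeated k-fold cross-validation.

#' Specify a one-vs-rest classifier family
#'
#' @param family `"svm"` (linear kernel, cost `C`), `"adaboost"`
#'   (discrete AdaBoost over depth-1 rpart stumps) or `"bayes_net"`
#'   (Gaussian naive Bayes; the closest widely available stand-in for an
#'   unspecified Bayes-network learner).
#' @param C SVM cost parameter (default 10)
#' @param nRounds AdaBoost rounds (default 100)
#' @return list of class `"classifierSpec"`
#' @export
classifierSpec <- function(family = c("svm", "adaboost", "bayes_net"),
                           C = 10, nRounds = 100L) {
  family <- match.arg(family)
  structure(list(family = family, C = C, nRounds = as.integer(nRounds)),
            class = "classifierSpec")
}

# ---- discrete AdaBoost with decision stumps -----------------------------

.fitAdaboost <- function(X, y01, nRounds) {
  # y01: 0/1 integer; internally works in {-1, +1}
  y <- ifelse(y01 == 1L, 1, -1)
  n <- length(y)
  w <- rep(1 / n, n)
  df <- data.frame(.y = factor(y, levels = c(-1, 1)), X,
                   check.names = FALSE)
  stumps <- list()
  alphas <- numeric()
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                               xval = 0, maxcompete = 0,
                               maxsurrogate = 0)
  for (m in seq_len(nRounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        method = "class", control = ctrl)
    pred <- as.numeric(as.character(predict(fit, df, type = "class")))
    err <- sum(w[pred != y])
    if (err >= 0.5 - 1e-12) break
    err <- max(err, 1e-12)
    a <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, a)
    w <- w * exp(-a * y * pred)
    w <- w / sum(w)
    if (err <= 1e-12) break
  }
  if (length(stumps) == 0) {
    # no stump beats weighted chance: fall back to the majority class
    list(type = "constant", value = as.integer(mean(y01) >= 0.5))
  } else {
    list(type = "adaboost", stumps = stumps, alphas = alphas)
  }
}

.predictAdaboost <- function(model, X) {
  if (model$type == "constant")
    return(rep(model$value, nrow(X)))
  df <- as.data.frame(X, check.names = FALSE)
  s <- numeric(nrow(X))
  for (m in seq_along(model$stumps)) {
    pred <- as.numeric(as.character(
      predict(model$stumps[[m]], df, type = "class")))
    s <- s + model$alphas[m] * pred
  }
  as.integer(s > 0)
}

# ---- per-family binary fit/predict --------------------------------------

.fitBinary <- function(X, y01, spec) {
  if (length(unique(y01)) < 2)
    return(list(type = "constant", value = y01[1]))
  switch(spec$family,
    svm = {
      fit <- e1071::svm(x = X, y = factor(y01, levels = c(0, 1)),
                        kernel = "linear", cost = spec$C, scale = FALSE)
      list(type = "svm", fit = fit)
    },
    adaboost = .fitAdaboost(X, y01, spec$nRounds),
    bayes_net = {
      keep <- which(apply(X, 2, function(v) stats::var(v) > 0))
      fit <- e1071::naiveBayes(x = as.data.frame(X[, keep, drop = FALSE],
                                                 check.names = FALSE),
                               y = factor(y01, levels = c(0, 1)))
      list(type = "bayes_net", fit = fit, keep = keep)
    })
}

.predictBinary <- function(model, X) {
  switch(model$type,
    constant = rep(model$value, nrow(X)),
    svm = as.integer(as.character(predict(model$fit, X))),
    adaboost = .predictAdaboost(model, X),
    bayes_net = {
      nd <- as.data.frame(X[, model$keep, drop = FALSE],
                          check.names = FALSE)
      as.integer(as.character(predict(model$fit, nd, type = "class")))
    })
}

#' Train one-vs-rest multilabel classifiers
#'
#' Fits one independent binary classifier per label. A label with no
#' positive (or no negative) training example gets a constant predictor
#' with a warning.
#'
#' @param X N x D feature matrix (e.g. from [featurizeCorpus()])
#' @param Y N x K binary label matrix
#' @param spec a [classifierSpec()]
#' @param seed RNG seed (the fitted families are deterministic given the
#'   data; the seed pins any internal randomness)
#' @return object of class `"ovrModel"`
#' @export
trainOvr <- function(X, Y, spec = classifierSpec(), seed = 1L) {
  if (nrow(X) != nrow(Y)) stop("feature/label row mismatch")
  if (nrow(X) < 2) stop("need at least 2 training items")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  set.seed(seed)
  K <- ncol(Y)
  models <- vector("list", K)
  for (k in seq_len(K)) {
    y <- Y[, k]
    if (sum(y) == 0)
      warning("label '", colnames(Y)[k],
              "' has no positive training example; it is never predicted")
    models[[k]] <- .fitBinary(X, y, spec)
  }
  structure(list(models = models, labelNames = colnames(Y), spec = spec),
            class = "ovrModel")
}

#' Predict label sets with a one-vs-rest model
#'
#' @param model an `"ovrModel"` from [trainOvr()]
#' @param X feature matrix with the training layout
#' @return list of predicted label-name vectors, one per row of `X`;
#'   attribute `"matrix"` carries the N x K binary prediction matrix
#' @export
predictOvr <- function(model, X) {
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  K <- length(model$models)
  P <- matrix(0L, nrow(X), K, dimnames = list(rownames(X),
                                              model$labelNames))
  for (k in seq_len(K)) P[, k] <- .predictBinary(model$models[[k]], X)
  out <- lapply(seq_len(nrow(X)), function(i)
    model$labelNames[P[i, ] == 1L])
  attr(out, "matrix") <- P
  out
}

#' Micro-averaged multilabel evaluation
#'
#' Pools counts over every item and label:
#' Precision = (total correct predicted labels) / (total predicted
#' labels); Recall = (total correct predicted labels) / (total true
#' labels); Micro-F1 = 2 P R / (P + R). A zero denominator yields 0 with
#' a warning, keeping averages defined.
#'
#' @param predicted list of predicted label sets (character vectors)
#' @param truth list of true label sets, same length
#' @return list with `precision`, `recall`, `microF1`, and the pooled
#'   counts `correct`, `totalPredicted`, `totalTrue`
#' @export
evaluateLabels <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  correct <- sum(mapply(function(p, t) length(intersect(p, t)),
                        predicted, truth))
  totPred <- sum(lengths(predicted))
  totTrue <- sum(lengths(truth))
  if (totPred == 0) warning("no labels predicted; precision set to 0")
  precision <- if (totPred > 0) correct / totPred else 0
  recall <- if (totTrue > 0) correct / totTrue else 0
  microF1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, microF1 = microF1,
       correct = correct, totalPredicted = totPred, totalTrue = totTrue)
}

# Subset a corpus to a prescription index vector, keeping the full herb
# table and label vocabulary (model constants).
#' @rdname corpus-accessors
#' @param idx integer vector of prescription indices
#' @export
subsetCorpus <- function(x, idx) {
  new("HerbCorpus", prescriptions = x@prescriptions[idx],
      herbs = x@herbs, labelNames = x@labelNames)
}

# Stratified fold assignment: items grouped by their corpus-wide most
# frequent label and dealt round-robin into folds after a shuffle.
.foldAssignment <- function(corpus, nFolds) {
  N <- nPrescriptions(corpus)
  labFreq <- colSums(labelMatrix(corpus))
  strat <- vapply(corpus@prescriptions, function(p) {
    if (length(p$labels) == 0) return(0L)
    p$labels[which.max(labFreq[p$labels])]
  }, 0L)
  fold <- integer(N)
  nxt <- 0L
  for (g in unique(strat)) {
    members <- sample(which(strat == g))
    fold[members] <- (nxt + seq_along(members) - 1L) %% nFolds + 1L
    nxt <- nxt + length(members)
  }
  fold
}

#' Repeated k-fold cross-validation of the classifier track
#'
#' For each repetition, items are shuffled into stratified folds; per
#' fold, TFIDF statistics are computed on the training split only, the
#' one-vs-rest model is trained and the held-out fold predicted. Counts
#' are pooled over the folds of a repetition, then the per-repetition
#' metrics are averaged.
#'
#' @param corpus a labeled [HerbCorpus-class]
#' @param mode feature mode for [featurizeCorpus()]
#' @param spec a [classifierSpec()]
#' @param nFolds number of folds (default 4)
#' @param repetitions number of shuffled repetitions (default 10)
#' @param seed RNG seed
#' @param vocab an [attributeVocabulary()]
#' @return list with averaged `precision`, `recall`, `microF1`, the
#'   per-repetition data.frame `perRep`, `nFolds` and `repetitions`
#' @export
crossValidate <- function(corpus, mode = "combined",
                          spec = classifierSpec(), nFolds = 4L,
                          repetitions = 10L, seed = 1L,
                          vocab = attributeVocabulary()) {
  N <- nPrescriptions(corpus)
  if (N < nFolds) stop("corpus smaller than the number of folds")
  set.seed(seed)
  truthAll <- lapply(corpus@prescriptions, function(p)
    corpus@labelNames[p$labels])
  perRep <- data.frame()
  for (r in seq_len(repetitions)) {
    fold <- .foldAssignment(corpus, nFolds)
    correct <- totPred <- totTrue <- 0
    for (f in seq_len(nFolds)) {
      trIdx <- which(fold != f)
      teIdx <- which(fold == f)
      if (length(teIdx) == 0) next
      train <- subsetCorpus(corpus, trIdx)
      test <- subsetCorpus(corpus, teIdx)
      if (any(colSums(labelMatrix(train)) == 0))
        warning("a label has no positives in the training fold")
      stats <- tfidfStats(train)
      ftr <- suppressWarnings(
        featurizeCorpus(train, mode, stats = stats, vocab = vocab))
      fte <- suppressWarnings(
        featurizeCorpus(test, mode, stats = stats, vocab = vocab))
      fit <- suppressWarnings(trainOvr(ftr$X, ftr$Y, spec,
                                       seed = seed + r))
      pred <- predictOvr(fit, fte$X)
      ev <- suppressWarnings(evaluateLabels(pred, truthAll[teIdx]))
      correct <- correct + ev$correct
      totPred <- totPred + ev$totalPredicted
      totTrue <- totTrue + ev$totalTrue
    }
    P <- if (totPred > 0) correct / totPred else 0
    R <- if (totTrue > 0) correct / totTrue else 0
    F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
    perRep <- rbind(perRep, data.frame(rep = r, precision = P,
                                       recall = R, microF1 = F1))
  }
  list(precision = mean(perRep$precision),
       recall = mean(perRep$recall),
       microF1 = mean(perRep$microF1),
       perRep = perRep, nFolds = nFolds, repetitions = repetitions)
}
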