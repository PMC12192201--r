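#' Confusion counts of binary hard calls
#'
#' Positive class = 1. Both inputs must be binary vectors of equal length.
#'
#' @param labels true 0/1 labels.
#' @param calls predicted 0/1 hard calls.
#' @return Named integer vector TP, TN, FP, FN.
#' @export
confusionCounts <- function(labels, calls) {
  if (length(labels) != length(calls)) stopf("labels and calls must have equal length")
  if (!all(labels %in% c(0, 1)) || !all(calls %in% c(0, 1)))
    stopf("labels and calls must be binary (0/1)")
  c(TP = sum(labels == 1 & calls == 1),
    TN = sum(labels == 0 & calls == 0),
    FP = sum(labels == 0 & calls == 1),
    FN = sum(labels == 1 & calls == 0))
}

#' Accuracy, sensitivity, specificity from confusion counts
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`.
#' A metric whose denominator is zero is undefined and reported as NaN
#' with a warning.
#'
#' @param counts named vector with TP, TN, FP, FN.
#' @return Named numeric vector acc, sen, spe.
#' @export
accSenSpe <- function(counts) {
  TP <- counts[["TP"]]; TN <- counts[["TN"]]; FP <- counts[["FP"]]; FN <- counts[["FN"]]
  acc <- (TP + TN) / (TP + TN + FP + FN)
  sen <- if (TP + FN > 0) TP / (TP + FN) else { warning("sensitivity undefined: no positives"); NaN }
  spe <- if (TN + FP > 0) TN / (TN + FP) else { warning("specificity undefined: no negatives"); NaN }
  c(acc = acc, sen = sen, spe = spe)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC traced over all score thresholds, which
#' equals the Mann-Whitney probability that a random positive outscores a
#' random negative, with ties counted 1/2. Computed via average ranks.
#'
#' @param labels 0/1 labels with both classes present.
#' @param scores numeric scores (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(labels, scores) {
  if (length(labels) != length(scores)) stopf("labels and scores must have equal length")
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary (0/1)")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified hold-out split
#'
#' Random split at `fraction`, stratified by label so class proportions are
#' preserved within +/- 1 subject; disjoint and exhaustive.
#'
#' @param labels 0/1 label vector (>= 2 subjects per class).
#' @param fraction training fraction (default 0.8).
#' @param seed RNG seed.
#' @return list(train, test) of indices into `labels`.
#' @export
splitHoldout <- function(labels, fraction = 0.8, seed = 1) {
  checkClassSizes(labels, 2L)
  withSeed(seed, {
    train <- integer(0)
    for (cl in c(0, 1)) {
      idx <- which(labels == cl)
      nTrain <- round(fraction * length(idx))
      train <- c(train, sample(idx, nTrain))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Stratified k-fold cross-validation splits
#'
#' @param labels 0/1 label vector.
#' @param k number of folds (<= smallest class size).
#' @param seed RNG seed.
#' @return list of k lists with `train` and `val` index vectors; every
#'   subject appears in exactly one validation fold.
#' @export
kFold <- function(labels, k = 5, seed = 1) {
  checkClassSizes(labels, k)
  withSeed(seed, {
    fold <- integer(length(labels))
    for (cl in c(0, 1)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    lapply(seq_len(k), function(i)
      list(train = which(fold != i), val = which(fold == i)))
  })
}

checkClassSizes <- function(labels, minSize) {
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary (0/1)")
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab < minSize))
    stopf("each class needs at least %d subjects (have %d / %d)",
          minSize, tab[1], tab[2])
  invisible(TRUE)
}

#' Evaluate a model on a set of labelled bags
#'
#' Hard calls threshold the positive-class probability at `threshold`
#' (default 0.5).
#'
#' @param model a [BagModel-class].
#' @param bags labelled [PatchBag-class] list with both classes present.
#' @param threshold operating point for ACC/SEN/SPE.
#' @return list(acc, sen, spe, auc, counts, n, threshold, prob,
#'   attention).
#' @export
evaluateBags <- function(model, bags, threshold = 0.5) {
  pred <- predictBags(model, bags)
  y <- pred$labels
  if (anyNA(y)) stopf("all bags must be labelled for evaluation")
  calls <- as.integer(pred$prob >= threshold)
  counts <- confusionCounts(y, calls)
  m <- accSenSpe(counts)
  list(acc = unname(m["acc"]), sen = unname(m["sen"]), spe = unname(m["spe"]),
       auc = aucScore(y, pred$prob), counts = as.list(counts),
       n = length(y), threshold = threshold,
       prob = pred$prob, attention = pred$attention)
}
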