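# Attention-aware global classifier and training. The bag probability
# decomposes as Theta(X) = g(phi(f(X))): f = PatchNet per instance (shared
# weights), phi = attention MIL pooling, g = this classifier. g treats the
# patch axis of the pooled representation as channels and squeezes it with
# two 3x3x3 conv layers before a fully-connected softmax head.

#' Build a bag-level classification model
#'
#' @param k bag size (patches per subject).
#' @param W patch width in voxels (even widths keep the pooled grid exact).
#' @param channels PatchNet channel counts `c(c1, c2, c3, c4)`.
#' @param attHidden hidden width of the descriptor-attention MLP; default
#'   `max(ceiling(k/4), 4)`.
#' @param sharedDescriptorMLP share the MLP between GAP and GMP paths.
#' @param classifierChannels the two conv widths of the global classifier.
#' @param flags ablation flags, subset of
#'   `c("no_patchnet_cnn", "no_attention", "no_fssa")`.
#' @param seed RNG seed for parameter initialization.
#' @return A [BagModel-class].
#' @export
newBagModel <- function(k, W, channels = c(32, 64, 128, 128),
                        attHidden = max(ceiling(k / 4), 4),
                        sharedDescriptorMLP = TRUE,
                        classifierChannels = c(16, 8),
                        flags = character(0), seed = 1) {
  known <- c("no_patchnet_cnn", "no_attention", "no_fssa")
  if (length(setdiff(flags, known)))
    stopf("unknown ablation flag(s): %s", paste(setdiff(flags, known), collapse = ", "))
  fl <- as.list(setNames(known %in% flags, known))
  k <- as.integer(k); W <- as.integer(W)
  if (W < 2L) stopf("patch width %d too small for the central pooling stage", W)
  w <- W %/% 2L
  cin <- if (fl$no_patchnet_cnn) NA_integer_ else channels[4]
  withSeed(seed, {
    pn <- newPatchNet(channels)
    am <- newAmidl(k, hidden = attHidden, shared = sharedDescriptorMLP)
    cc1 <- classifierChannels[1]; cc2 <- classifierChannels[2]
    cl <- list(conv1 = newConv(k, cc1), bn1 = newBN(cc1),
               conv2 = newConv(cc1, cc2), bn2 = newBN(cc2),
               fc = list(W = matrix(rnorm(2 * cc2 * w^3, sd = sqrt(1 / (cc2 * w^3))),
                                    2, cc2 * w^3),
                         b = rep(0, 2)))
    new("BagModel", patchnet = pn, amidl = am, classifier = cl,
        config = list(k = k, W = W, w = w, channels = channels,
                      attHidden = attHidden,
                      sharedDescriptorMLP = sharedDescriptorMLP,
                      classifierChannels = classifierChannels,
                      flags = fl, seed = seed))
  })
}

#' Build an ablation variant of the full model
#'
#' `no_patchnet_cnn` replaces PatchNet by a fixed per-patch embedding
#' (2x2x2 average pooling, effect = mean intensity); `no_attention`
#' replaces the spatial and patch attention (identity attention /
#' unweighted pooling); `no_fssa` skips the swarm refinement stage in the
#' pipeline. No flags returns the full model.
#'
#' @param flags character vector of flags.
#' @param ... passed to [newBagModel()].
#' @return A [BagModel-class].
#' @export
ablationVariant <- function(flags = character(0), ...) {
  newBagModel(..., flags = flags)
}

# classifier forward with caches; x is the pooled (w, w, w, k) tensor
clForward <- function(x, cl, training = FALSE) {
  z1 <- conv3d(x, cl$conv1$W, cl$conv1$b)
  b1 <- bnForward(list(z1), cl$bn1, training); cl$bn1 <- b1$bn
  a1 <- reluForward(b1$ys[[1]])
  z2 <- conv3d(a1, cl$conv2$W, cl$conv2$b)
  b2 <- bnForward(list(z2), cl$bn2, training); cl$bn2 <- b2$bn
  a2 <- reluForward(b2$ys[[1]])
  flat <- as.numeric(a2)
  logits <- denseForward(flat, cl$fc$W, cl$fc$b)
  probs <- softmaxProbs(logits)
  list(probs = probs, logits = logits, cl = cl,
       cache = list(x = x, b1 = b1$cache, a1 = a1, b2 = b2$cache, a2 = a2,
                    flat = flat, probs = probs))
}

clBackward <- function(glogits, cl, cache) {
  db <- denseBackward(cache$flat, cl$fc$W, glogits)
  ga2 <- array(db$gx, dim(cache$a2))
  gz2 <- reluBackward(ga2, cache$a2)
  bb2 <- bnBackward(list(gz2), cache$b2)
  cb2 <- conv3dBackward(cache$a1, cl$conv2$W, bb2$gxs[[1]])
  gz1 <- reluBackward(cb2$gx, cache$a1)
  bb1 <- bnBackward(list(gz1), cache$b1)
  cb1 <- conv3dBackward(cache$x, cl$conv1$W, bb1$gxs[[1]])
  list(gx = cb1$gx,
       grads = list(conv1 = list(W = cb1$gW, b = cb1$gb),
                    bn1 = list(gamma = bb1$ggamma, beta = bb1$gbeta),
                    conv2 = list(W = cb2$gW, b = cb2$gb),
                    bn2 = list(gamma = bb2$ggamma, beta = bb2$gbeta),
                    fc = list(W = db$gW, b = db$gb)))
}

#' Global classifier forward pass
#'
#' Runs the attention-aware global classifier on a pooled bag
#' representation in inference mode: two conv+BN+ReLU stages squeezing the
#' patch axis, flatten, fully-connected softmax head.
#'
#' @param G numeric array `(w, w, w, k)`.
#' @param model a [BagModel-class].
#' @return list(probPositive, probs, logits).
#' @export
globalClassifierForward <- function(G, model) {
  stopifnot(is(model, "BagModel"))
  G <- asMap4(G)
  if (dim(G)[4] != model@config$k)
    stopf("pooled representation has %d patch maps, model expects k = %d",
          dim(G)[4], model@config$k)
  out <- clForward(G, model@classifier, training = FALSE)
  list(probPositive = out$probs[2], probs = out$probs, logits = out$logits)
}

# Full model forward. Returns prediction, all caches and the model (with
# updated BN running moments when training).
fullForward <- function(model, patches, training = FALSE) {
  fl <- model@config$flags
  if (length(patches) != model@config$k)
    stopf("bag size %d does not match model k = %d", length(patches), model@config$k)
  if (fl$no_patchnet_cnn) {
    emb <- fixedEmbeddingBag(patches)
    feats <- emb$features; effect <- emb$effect; pnCache <- NULL
  } else {
    pno <- patchnetForwardBag(patches, model@patchnet, training = training,
                              spatial = !fl$no_attention)
    model@patchnet <- pno$pn
    feats <- pno$features; effect <- pno$effect; pnCache <- pno$cache
  }
  if (fl$no_attention) {
    G <- compressAndStack(feats)
    Gw <- G
    att <- rep(1 / length(feats), length(feats))
    amCache <- list(nChannels = vapply(feats, function(f) dim(asMap4(f))[4], integer(1)),
                    d = dim(G))
  } else {
    amo <- amidlForward(feats, effect, model@amidl)
    Gw <- amo$global; att <- amo$attention; amCache <- amo$cache
  }
  co <- clForward(Gw, model@classifier, training = training)
  model@classifier <- co$cl
  list(probs = co$probs, logits = co$logits, attention = att,
       model = model,
       caches = list(pn = pnCache, am = amCache, cl = co$cache))
}

# Backward for one bag given forward caches; label in {0,1}; weight scales
# the loss term. Returns nested grads (patchnet/amidl/classifier).
fullBackward <- function(model, caches, label, weight = 1) {
  fl <- model@config$flags
  probs <- caches$cl$probs
  onehot <- c(label == 0, label == 1)
  glogits <- weight * (probs - onehot)
  cb <- clBackward(glogits, model@classifier, caches$cl)
  g <- list(classifier = cb$grads)
  k <- model@config$k
  if (fl$no_attention) {
    d <- caches$am$d; nv <- prod(d[1:3])
    gG <- matrix(cb$gx, nv, k)
    gfeats <- lapply(seq_len(k), function(i) {
      C <- caches$am$nChannels[i]
      array(rep(gG[, i] / C, C), c(d[1:3], C))
    })
    geffect <- rep(0, k)
  } else {
    ab <- amidlBackward(cb$gx, model@amidl, caches$am)
    g$amidl <- ab$gparams
    gfeats <- ab$gfeats
    geffect <- ab$geffect
  }
  if (!fl$no_patchnet_cnn)
    g$patchnet <- patchnetBackwardBag(gfeats, geffect, model@patchnet, caches$pn)
  g
}

#' Predict bags with a trained model
#'
#' @param model a [BagModel-class].
#' @param bags list of [PatchBag-class].
#' @return list(prob = numeric, attention = k x n matrix, labels =
#'   integer bag labels (NA where unset)).
#' @export
predictBags <- function(model, bags) {
  outs <- lapply(bags, function(b) fullForward(model, b@patches, training = FALSE))
  list(prob = vapply(outs, function(o) o$probs[2], numeric(1)),
       attention = vapply(outs, `[[`, numeric(model@config$k), "attention"),
       labels = vapply(bags, function(b) b@label, integer(1)))
}

#' Bag-level forward pass
#'
#' Composes PatchNet per instance, attention MIL pooling and the global
#' classifier for one bag, in inference mode.
#'
#' @param bag a [PatchBag-class] whose size matches the model's k.
#' @param model a [BagModel-class].
#' @return list(probPositive, probs, logits, attention).
#' @export
bagForward <- function(bag, model) {
  stopifnot(is(bag, "PatchBag"), is(model, "BagModel"))
  out <- fullForward(model, bag@patches, training = FALSE)
  list(probPositive = out$probs[2], probs = out$probs, logits = out$logits,
       attention = out$attention)
}

#' Mean cross-entropy loss of bag predictions
#'
#' `L = -(1/N) * sum_n log P(Y_n | X_n)`.
#'
#' @param predictions list of predictions as returned by [bagForward()]
#'   (anything with a `probs` element, or a bare probability pair).
#' @param labels integer 0/1 labels of the same length.
#' @return Scalar loss.
#' @export
crossEntropyLoss <- function(predictions, labels) {
  if (!length(predictions) || length(predictions) != length(labels))
    stopf("predictions and labels must be non-empty and of equal length")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0 or 1")
  p <- vapply(seq_along(predictions), function(i) {
    pr <- predictions[[i]]
    probs <- if (is.list(pr)) pr$probs else pr
    probs[labels[i] + 1]
  }, numeric(1))
  -mean(log(pmax(p, 1e-300)))
}

# ---- parameter flattening ------------------------------------------------

paramPaths <- function(model) {
  fl <- model@config$flags
  paths <- list()
  if (!fl$no_patchnet_cnn) {
    for (ly in c("conv1", "conv2", "conv3", "conv4"))
      for (nm in c("W", "b")) paths <- c(paths, list(c("patchnet", ly, nm)))
    for (ly in c("bn1", "bn2", "bn3", "bn4"))
      for (nm in c("gamma", "beta")) paths <- c(paths, list(c("patchnet", ly, nm)))
    if (!fl$no_attention) {
      paths <- c(paths, list(c("patchnet", "att", "W"), c("patchnet", "att", "b"),
                             c("patchnet", "eff", "w"), c("patchnet", "eff", "b")))
    }
  }
  if (!fl$no_attention) {
    nms <- c("w0", "b0", "w1", "b1")
    if (!model@config$sharedDescriptorMLP) nms <- c(nms, "w0m", "b0m", "w1m", "b1m")
    for (nm in nms) paths <- c(paths, list(c("amidl", nm)))
  }
  for (ly in c("conv1", "conv2"))
    for (nm in c("W", "b")) paths <- c(paths, list(c("classifier", ly, nm)))
  for (ly in c("bn1", "bn2"))
    for (nm in c("gamma", "beta")) paths <- c(paths, list(c("classifier", ly, nm)))
  paths <- c(paths, list(c("classifier", "fc", "W"), c("classifier", "fc", "b")))
  paths
}

getLeaf <- function(model, p) {
  obj <- slot(model, p[1])
  if (length(p) > 1) obj <- obj[[p[-1]]]
  obj
}

setLeaf <- function(model, p, value) {
  s <- slot(model, p[1])
  old <- s[[p[-1]]]
  if (is.matrix(old)) value <- matrix(value, nrow(old), ncol(old))
  s[[p[-1]]] <- value
  slot(model, p[1]) <- s
  model
}

paramsToVector <- function(model, paths = paramPaths(model)) {
  unlist(lapply(paths, function(p) as.numeric(getLeaf(model, p))))
}

vectorToModel <- function(model, vec, paths = paramPaths(model)) {
  off <- 0L
  for (p in paths) {
    n <- length(getLeaf(model, p))
    model <- setLeaf(model, p, vec[off + seq_len(n)])
    off <- off + n
  }
  stopifnot(off == length(vec))
  model
}

gradsToVector <- function(g, model, paths = paramPaths(model)) {
  unlist(lapply(paths, function(p) {
    v <- g[[p]]
    if (is.null(v)) rep(0, length(getLeaf(model, p))) else as.numeric(v)
  }))
}

# ---- training ------------------------------------------------------------

#' Train a bag model by minimizing the cross-entropy loss
#'
#' Mini-batch gradient training (Adam by default) of all model parameters,
#' with early stopping on the validation loss. BN layers use per-bag batch
#' statistics at train time and running moments at evaluation time. Fully
#' seeded runs are reproducible on one machine.
#'
#' @param model a [BagModel-class].
#' @param trainBags,valBags lists of labelled [PatchBag-class] objects.
#' @param lr learning rate (default 1e-3).
#' @param epochs maximum epochs (default 100).
#' @param batchSize bags per gradient step (default 8).
#' @param patience early-stopping patience in epochs (default 15).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param classWeights optional numeric(2) loss weights for classes 0/1;
#'   `"balanced"` uses inverse frequencies from the training labels.
#' @param seed RNG seed for shuffling.
#' @param verbose print per-epoch progress.
#' @return list(model = best-validation-loss model, history = data.frame
#'   with epoch, train_loss, val_loss, val_auc).
#' @export
trainBagModel <- function(model, trainBags, valBags, lr = 1e-3, epochs = 100,
                          batchSize = 8, patience = 15,
                          optimizer = c("adam", "sgd"), classWeights = NULL,
                          seed = 1, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  if (!length(trainBags) || !length(valBags)) stopf("training and validation sets must be non-empty")
  yTrain <- vapply(trainBags, function(b) b@label, integer(1))
  yVal <- vapply(valBags, function(b) b@label, integer(1))
  if (anyNA(yTrain) || anyNA(yVal)) stopf("all bags must be labelled")
  if (identical(classWeights, "balanced")) {
    tab <- table(factor(yTrain, levels = c(0, 1)))
    classWeights <- as.numeric(length(yTrain) / (2 * pmax(tab, 1)))
  }
  wOf <- function(y) if (is.null(classWeights)) 1 else classWeights[y + 1]

  paths <- paramPaths(model)
  vec <- paramsToVector(model, paths)
  mAdam <- vAdam <- rep(0, length(vec)); tAdam <- 0
  beta1 <- 0.9; beta2 <- 0.999; epsAdam <- 1e-8

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_auc = numeric(0))
  best <- list(loss = Inf, model = model, epoch = 0L)
  sinceBest <- 0L

  withSeed(seed, {
    for (epoch in seq_len(epochs)) {
      ord <- sample(length(trainBags))
      epochLoss <- 0
      nb <- 0L
      for (start in seq(1, length(ord), by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1, length(ord))]
        gvec <- rep(0, length(vec))
        bloss <- 0
        for (i in idx) {
          fw <- fullForward(model, trainBags[[i]]@patches, training = TRUE)
          model <- fw$model       # BN running moments advance
          y <- yTrain[i]
          pTrue <- max(fw$probs[y + 1], 1e-300)
          bloss <- bloss + wOf(y) * (-log(pTrue))
          g <- fullBackward(model, fw$caches, y, weight = wOf(y) / length(idx))
          gvec <- gvec + gradsToVector(g, model, paths)
        }
        bloss <- bloss / length(idx)
        if (!is.finite(bloss))
          stopf("non-finite training loss at epoch %d, batch starting %d", epoch, start)
        if (optimizer == "adam") {
          tAdam <- tAdam + 1
          mAdam <- beta1 * mAdam + (1 - beta1) * gvec
          vAdam <- beta2 * vAdam + (1 - beta2) * gvec^2
          mh <- mAdam / (1 - beta1^tAdam)
          vh <- vAdam / (1 - beta2^tAdam)
          vec <- vec - lr * mh / (sqrt(vh) + epsAdam)
        } else {
          vec <- vec - lr * gvec
        }
        model <- vectorToModel(model, vec, paths)
        epochLoss <- epochLoss + bloss; nb <- nb + 1L
      }
      valPred <- predictBags(model, valBags)
      valLoss <- -mean(log(pmax(ifelse(yVal == 1, valPred$prob, 1 - valPred$prob), 1e-300)))
      valAuc <- if (length(unique(yVal)) == 2) aucScore(yVal, valPred$prob) else NA_real_
      history <- rbind(history, data.frame(epoch = epoch, train_loss = epochLoss / nb,
                                           val_loss = valLoss, val_auc = valAuc))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  auc %s", epoch,
                        epochLoss / nb, valLoss, format(valAuc, digits = 3)))
      if (valLoss < best$loss - 1e-12) {
        best <- list(loss = valLoss, model = model, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= patience) break
      }
    }
  })
  list(model = best$model, history = history, bestEpoch = best$epoch)
}
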