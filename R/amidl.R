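# Attention MIL pooling: compress each patch's channels, derive per-patch
# GAP/GMP descriptors, pass them through a shared per-patch scalar MLP
# (two 1x1x1 conv layers: 1 -> h -> 1 channels, so there is no cross-patch
# mixing and pooling stays permutation-equivariant), fuse with the effect
# scores through a sigmoid, and scale each patch's compressed map by its
# attention weight.

#' Compress per-patch features and stack into the global representation
#'
#' Each patch's `C` channels are averaged to one `w^3` map; maps are
#' stacked in bag order into an array `(w, w, w, k)`.
#'
#' @param features list of k numeric `(w, w, w, C)` arrays sharing one
#'   shape.
#' @return Numeric array `(w, w, w, k)`.
#' @export
compressAndStack <- function(features) {
  stopifnot(length(features) >= 1L)
  dims <- lapply(features, function(f) dim(asMap4(f)))
  if (any(vapply(dims, function(d) !identical(d, dims[[1]]), logical(1))))
    stopf("all patch feature tensors must share one shape")
  maps <- lapply(features, channelAvgPool)
  array(unlist(maps), c(dim(maps[[1]]), length(maps)))
}

#' Descriptor attention from global average / max pooling
#'
#' Reduces each patch map of `G` to its global average (GAP) and global max
#' (GMP) scalar, then passes each descriptor through the two-layer 1x1x1
#' convolution stack `linear -> ReLU -> linear` (weights `W0, b0, W1, b1`
#' shared between the two paths by default), yielding the pre-sigmoid
#' attention vectors `A_average` and `A_max`, each of length k.
#'
#' @param G numeric array `(w, w, w, k)` from [compressAndStack()].
#' @param params list with `w0, b0` (numeric(h)) and `w1` (numeric(h)),
#'   `b1` (numeric(1)); optionally `w0m, b0m, w1m, b1m` for an unshared
#'   max path.
#' @return list(Aaverage, Amax): numeric(k) each.
#' @export
descriptorAttention <- function(G, params) {
  G <- asMap4(G)
  k <- dim(G)[4]
  nv <- prod(dim(G)[1:3])
  m <- matrix(G, nv, k)
  gap <- colMeans(m)
  gmp <- apply(m, 2, max)
  pa <- scalarMLP(gap, params$w0, params$b0, params$w1, params$b1)
  pm <- if (!is.null(params$w0m))
    scalarMLP(gmp, params$w0m, params$b0m, params$w1m, params$b1m)
  else
    scalarMLP(gmp, params$w0, params$b0, params$w1, params$b1)
  list(Aaverage = pa$out, Amax = pm$out)
}

# per-patch scalar MLP 1 -> h -> 1; x numeric(k)
scalarMLP <- function(x, w0, b0, w1, b1) {
  if (length(w0) != length(b0) || length(w0) != length(w1) || length(b1) != 1L)
    stopf("descriptor MLP parameter shapes are inconsistent")
  pre <- outer(x, w0) + matrix(b0, length(x), length(b0), byrow = TRUE)  # k x h
  h <- pmax(pre, 0)
  list(out = as.numeric(h %*% w1) + b1, h = h, x = x)
}

scalarMLPBackward <- function(gout, cache, w0, w1) {
  h <- cache$h
  gw1 <- as.numeric(crossprod(h, gout))
  gb1 <- sum(gout)
  gh <- outer(gout, w1) * (h > 0)       # k x h
  gw0 <- as.numeric(crossprod(gh, cache$x))
  gb0 <- colSums(gh)
  gx <- as.numeric(gh %*% w0)
  list(gx = gx, gw0 = gw0, gb0 = gb0, gw1 = gw1, gb1 = gb1)
}

#' Fuse the attention components into the patch attention map
#'
#' `A_patch = sigmoid(A_average + A_max + a)` element-wise, where `a` is
#' the effect vector; all three must have equal length k.
#'
#' @param Aaverage,Amax pre-sigmoid attention vectors.
#' @param a effect vector.
#' @return Numeric(k) with entries in (0, 1).
#' @export
fuseAttention <- function(Aaverage, Amax, a) {
  if (length(Aaverage) != length(Amax) || length(Amax) != length(a))
    stopf("attention components must have equal length")
  sigmoid(Aaverage + Amax + a)
}

#' Scale patch maps by the patch attention weights
#'
#' Patch i's compressed map is multiplied by `weights[i]`; shape is
#' preserved.
#'
#' @param G numeric array `(w, w, w, k)`.
#' @param weights numeric(k).
#' @return Array of the same shape.
#' @export
applyPatchAttention <- function(G, weights) {
  G <- asMap4(G)
  if (dim(G)[4] != length(weights))
    stopf("number of patch maps (%d) does not match weights (%d)",
          dim(G)[4], length(weights))
  sweep(G, 4, weights, "*")
}

#' Attention MIL pooling of a bag's patch features
#'
#' Composition [compressAndStack()] -> [descriptorAttention()] ->
#' [fuseAttention()] -> [applyPatchAttention()]. Returns the
#' attention-weighted global feature plus the patch attention map (kept for
#' interpretability: high-weight patches mark the discriminative sites).
#'
#' @param features list of k `(w, w, w, C)` feature tensors.
#' @param effect numeric(k) effect scores.
#' @param params descriptor MLP parameters (see [descriptorAttention()]).
#' @return list(global = `(w, w, w, k)` array, attention = numeric(k),
#'   components = list(Aaverage, Amax, effect)).
#' @export
amidlPool <- function(features, effect, params) {
  G <- compressAndStack(features)
  if (length(effect) != dim(G)[4])
    stopf("effect vector length must equal the bag size")
  da <- descriptorAttention(G, params)
  att <- fuseAttention(da$Aaverage, da$Amax, effect)
  list(global = applyPatchAttention(G, att), attention = att,
       components = list(Aaverage = da$Aaverage, Amax = da$Amax, effect = effect))
}

newAmidl <- function(k, hidden = max(ceiling(k / 4), 4), shared = TRUE) {
  p <- list(w0 = rnorm(hidden, sd = 1), b0 = rep(0, hidden),
            w1 = rnorm(hidden, sd = 1 / sqrt(hidden)), b1 = 0)
  if (!shared) {
    p$w0m <- rnorm(hidden, sd = 1); p$b0m <- rep(0, hidden)
    p$w1m <- rnorm(hidden, sd = 1 / sqrt(hidden)); p$b1m <- 0
  }
  p
}

# Forward with caches for training; mirrors amidlPool.
amidlForward <- function(features, effect, params) {
  G <- compressAndStack(features)
  d <- dim(G); k <- d[4]; nv <- prod(d[1:3])
  m <- matrix(G, nv, k)
  gap <- colMeans(m)
  argv <- max.col(t(m), ties.method = "first")   # argmax voxel per patch
  gmp <- m[cbind(argv, seq_len(k))]
  shared <- is.null(params$w0m)
  ca <- scalarMLP(gap, params$w0, params$b0, params$w1, params$b1)
  cm <- if (shared) scalarMLP(gmp, params$w0, params$b0, params$w1, params$b1)
        else scalarMLP(gmp, params$w0m, params$b0m, params$w1m, params$b1m)
  s <- ca$out + cm$out + effect
  att <- sigmoid(s)
  Gw <- sweep(G, 4, att, "*")
  list(global = Gw, attention = att,
       cache = list(G = G, m = m, d = d, gap = gap, gmp = gmp, argv = argv,
                    ca = ca, cm = cm, att = att, shared = shared,
                    nChannels = vapply(features, function(f) dim(asMap4(f))[4],
                                       integer(1))))
}

# Backward: gGw gradient w.r.t. the weighted global feature. Returns
# gradients w.r.t. each patch's attended features (through the compression),
# the effect vector, and the MLP parameters.
amidlBackward <- function(gGw, params, cache, featureDims) {
  d <- cache$d; k <- d[4]; nv <- prod(d[1:3])
  gGw <- matrix(gGw, nv, k)
  att <- cache$att
  gatt <- colSums(gGw * cache$m)
  gm <- sweep(gGw, 2, att, "*")
  gs <- gatt * att * (1 - att)
  geffect <- gs
  ba <- scalarMLPBackward(gs, cache$ca, params$w0, params$w1)
  if (cache$shared) {
    bm <- scalarMLPBackward(gs, cache$cm, params$w0, params$w1)
    gpar <- list(w0 = ba$gw0 + bm$gw0, b0 = ba$gb0 + bm$gb0,
                 w1 = ba$gw1 + bm$gw1, b1 = ba$gb1 + bm$gb1)
  } else {
    bm <- scalarMLPBackward(gs, cache$cm, params$w0m, params$w1m)
    gpar <- list(w0 = ba$gw0, b0 = ba$gb0, w1 = ba$gw1, b1 = ba$gb1,
                 w0m = bm$gw0, b0m = bm$gb0, w1m = bm$gw1, b1m = bm$gb1)
  }
  # descriptor paths back into the compressed maps
  gm <- gm + matrix(rep(ba$gx / nv, each = nv), nv, k)    # GAP path
  gm[cbind(cache$argv, seq_len(k))] <-
    gm[cbind(cache$argv, seq_len(k))] + bm$gx             # GMP path
  # compression (channel average) back into per-patch features
  gfeats <- lapply(seq_len(k), function(i) {
    C <- cache$nChannels[i]
    array(rep(gm[, i] / C, C), c(d[1:3], C))
  })
  list(gfeats = gfeats, geffect = geffect, gparams = gpar)
}
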