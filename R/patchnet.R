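# PatchNet: per-patch feature extractor. Architecture (all kernels 3x3x3,
# pad 1, BN + ReLU after each conv; one 2x2x2 max-pool "in the center"):
#   Conv1(1 -> c1) -> Conv2(c1 -> c2) -> MaxPool/2 ->
#   Conv3(c2 -> c3) -> Conv4(c3 -> c4)
# followed by an embedded spatial attention block on the Conv4 maps and two
# branches: the attended feature maps themselves (into MIL pooling) and a
# scalar effect score (global average pool -> linear) expressing the
# patch's capacity to activate the bag label.

#' Max pooling along the channel axis
#'
#' `out[w,h,l] = max_c F[w,h,l,c]`.
#'
#' @param F numeric array `(w, w, w, C)`.
#' @return Numeric `w x w x w` array.
#' @export
channelMaxPool <- function(F) {
  F <- asMap4(F)
  d <- dim(F)
  m <- matrix(F, prod(d[1:3]), d[4])
  array(do.call(pmax, asplit(m, 2)), d[1:3])
}

#' Average pooling along the channel axis
#'
#' `out[w,h,l] = mean_c F[w,h,l,c]`.
#'
#' @inheritParams channelMaxPool
#' @return Numeric `w x w x w` array.
#' @export
channelAvgPool <- function(F) {
  F <- asMap4(F)
  d <- dim(F)
  array(rowMeans(matrix(F, prod(d[1:3]), d[4])), d[1:3])
}

#' Spatial attention map of a feature tensor
#'
#' Concatenates the channel-max and channel-average pooled maps into a
#' 2-channel tensor, applies a 3x3x3 convolution (stride 1, padding 1)
#' mapping 2 channels to 1, and squashes with the sigmoid, yielding a map
#' in (0, 1) with the feature maps' spatial size.
#'
#' @param F numeric array `(w, w, w, C)`.
#' @param W conv weight matrix `1 x 54` (see [convWeightMatrix()]).
#' @param b bias, numeric(1).
#' @return Numeric `w x w x w` array with entries in (0, 1).
#' @export
spatialAttention <- function(F, W, b) {
  F <- asMap4(F)
  if (!is.matrix(W) || nrow(W) != 1L || ncol(W) != 54L)
    stopf("spatial attention conv must map 2 channels to 1 (W is 1 x 54)")
  d <- dim(F)[1:3]
  cc <- array(c(channelMaxPool(F), channelAvgPool(F)), c(d, 2L))
  pre <- conv3d(cc, W, b)
  array(sigmoid(pre), d)
}

#' Apply a spatial attention map to a feature tensor
#'
#' Every channel is multiplied voxel-wise by the map: `F'_c = F_c * A`.
#'
#' @param F numeric array `(w, w, w, C)`.
#' @param A numeric `w x w x w` array.
#' @return Array of the same shape as `F`.
#' @export
applySpatialAttention <- function(F, A) {
  F <- asMap4(F)
  if (!identical(dim(F)[1:3], dim(A)[1:3]))
    stopf("attention map shape %s does not match features %s",
          paste(dim(A), collapse = "x"), paste(dim(F), collapse = "x"))
  F * as.numeric(A)   # column recycling = per-channel broadcast
}

# Parameter set for one PatchNet; channels = c(c1, c2, c3, c4)
newPatchNet <- function(channels = c(32, 64, 128, 128)) {
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]; c4 <- channels[4]
  list(conv1 = newConv(1, c1), bn1 = newBN(c1),
       conv2 = newConv(c1, c2), bn2 = newBN(c2),
       conv3 = newConv(c2, c3), bn3 = newBN(c3),
       conv4 = newConv(c3, c4), bn4 = newBN(c4),
       att = newConv(2, 1),
       eff = list(w = rnorm(c4, sd = sqrt(1 / c4)), b = 0))
}

#' Forward pass of PatchNet for a single patch
#'
#' Runs the four-layer 3D CNN with the embedded spatial attention block in
#' inference mode (normalization layers use running moments), returning the
#' spatially-attended Conv4 features and the scalar effect score.
#'
#' @param patch numeric `W x W x W` array; `W >= 2` so the central pooling
#'   stage has input.
#' @param pn PatchNet parameter list (e.g. from [newBagModel()]'s
#'   `patchnet` component).
#' @return list(features = `(w, w, w, c4)` array with `w = floor(W/2)`,
#'   effect = scalar, attention = `(w, w, w)` spatial attention map).
#' @export
patchnetForward <- function(patch, pn) {
  out <- patchnetForwardBag(list(patch), pn, training = FALSE)
  list(features = out$features[[1]], effect = out$effect[1],
       attention = out$attention[[1]])
}

# Forward over the k patches of one bag. BN statistics are computed jointly
# over the bag's instances (the k patches of one subject are the
# normalization batch). Returns caches sufficient for the backward pass.
# `spatial = FALSE` (no_attention ablation) skips the attention block and
# returns the raw post-ReLU Conv4 maps.
patchnetForwardBag <- function(patches, pn, training = FALSE, spatial = TRUE) {
  if (min(dim(patches[[1]])) < 2L)
    stopf("patch width %d too small for the pooling stage", min(dim(patches[[1]])))
  x0 <- lapply(patches, asMap4)
  z1 <- lapply(x0, function(x) conv3d(x, pn$conv1$W, pn$conv1$b))
  b1 <- bnForward(z1, pn$bn1, training); pn$bn1 <- b1$bn
  a1 <- lapply(b1$ys, reluForward)
  z2 <- lapply(a1, function(x) conv3d(x, pn$conv2$W, pn$conv2$b))
  b2 <- bnForward(z2, pn$bn2, training); pn$bn2 <- b2$bn
  a2 <- lapply(b2$ys, reluForward)
  pl <- lapply(a2, maxPool3d)
  p2 <- lapply(pl, `[[`, "y")
  z3 <- lapply(p2, function(x) conv3d(x, pn$conv3$W, pn$conv3$b))
  b3 <- bnForward(z3, pn$bn3, training); pn$bn3 <- b3$bn
  a3 <- lapply(b3$ys, reluForward)
  z4 <- lapply(a3, function(x) conv3d(x, pn$conv4$W, pn$conv4$b))
  b4 <- bnForward(z4, pn$bn4, training); pn$bn4 <- b4$bn
  a4 <- lapply(b4$ys, reluForward)

  if (spatial) {
    attc <- lapply(a4, function(F) {
      d <- dim(F)
      nv <- prod(d[1:3])
      m <- matrix(F, nv, d[4])
      argc <- max.col(m, ties.method = "first")
      fmax <- m[cbind(seq_len(nv), argc)]
      favg <- rowMeans(m)
      cc <- array(c(fmax, favg), c(d[1:3], 2L))
      pre <- conv3d(cc, pn$att$W, pn$att$b)
      A <- sigmoid(as.numeric(pre))
      Fp <- m * A
      list(Fp = array(Fp, d), A = array(A, d[1:3]), argc = argc, cc = cc, m = m)
    })
    feats <- lapply(attc, `[[`, "Fp")
    amaps <- lapply(attc, `[[`, "A")
  } else {
    attc <- NULL
    feats <- a4
    amaps <- lapply(a4, function(F) array(1, dim(F)[1:3]))
  }

  # effect branch: GAP over the (attended) Conv4 maps -> linear -> scalar
  gaps <- lapply(feats, function(F) colMeans(matrix(F, prod(dim(F)[1:3]), dim(F)[4])))
  effect <- vapply(gaps, function(g) sum(pn$eff$w * g) + pn$eff$b, numeric(1))

  list(features = feats, effect = effect,
       attention = amaps,
       pn = pn,
       cache = list(x0 = x0, b1 = b1$cache, a1 = a1, b2 = b2$cache, a2 = a2,
                    plIdx = lapply(pl, `[[`, "idx"), p2 = p2,
                    b3 = b3$cache, a3 = a3, b4 = b4$cache, a4 = a4,
                    attc = attc, gaps = gaps, feats = feats, spatial = spatial))
}

# Backward through the bag-level PatchNet forward. gfeats: list of
# gradients w.r.t. the attended features; geffect: numeric(k) gradient
# w.r.t. the effect scores. Returns parameter gradients (summed over the
# shared instances) — input gradients are not needed (patches are data).
patchnetBackwardBag <- function(gfeats, geffect, pn, cache) {
  k <- length(gfeats)
  g <- list(conv1 = list(W = 0 * pn$conv1$W, b = 0 * pn$conv1$b),
            bn1 = list(gamma = 0 * pn$bn1$gamma, beta = 0 * pn$bn1$beta),
            conv2 = list(W = 0 * pn$conv2$W, b = 0 * pn$conv2$b),
            bn2 = list(gamma = 0 * pn$bn2$gamma, beta = 0 * pn$bn2$beta),
            conv3 = list(W = 0 * pn$conv3$W, b = 0 * pn$conv3$b),
            bn3 = list(gamma = 0 * pn$bn3$gamma, beta = 0 * pn$bn3$beta),
            conv4 = list(W = 0 * pn$conv4$W, b = 0 * pn$conv4$b),
            bn4 = list(gamma = 0 * pn$bn4$gamma, beta = 0 * pn$bn4$beta),
            att = list(W = 0 * pn$att$W, b = 0 * pn$att$b),
            eff = list(w = 0 * pn$eff$w, b = 0))

  # effect branch adds to the (attended) feature gradients
  gfeats <- lapply(seq_len(k), function(i) {
    d <- dim(cache$feats[[i]]); nv <- prod(d[1:3])
    g$eff$w <<- g$eff$w + geffect[i] * cache$gaps[[i]]
    g$eff$b <<- g$eff$b + geffect[i]
    extra <- matrix(rep(geffect[i] * pn$eff$w / nv, each = nv), nv, d[4])
    gfeats[[i]] + array(extra, d)
  })

  if (cache$spatial) {
    # spatial attention block backward -> gradient w.r.t. a4
    ga4 <- vector("list", k)
    for (i in seq_len(k)) {
      at <- cache$attc[[i]]
      d <- dim(at$Fp); nv <- prod(d[1:3]); C <- d[4]
      gFp <- matrix(gfeats[[i]], nv, C)
      A <- as.numeric(at$A)
      gA <- rowSums(gFp * at$m)            # sum over channels of gF' * F
      gm <- gFp * A                        # direct path
      gpre <- gA * A * (1 - A)             # sigmoid backward
      cb <- conv3dBackward(at$cc, pn$att$W, array(gpre, c(d[1:3], 1L)))
      g$att$W <- g$att$W + cb$gW
      g$att$b <- g$att$b + cb$gb
      gcc <- cb$gx
      gfmax <- as.numeric(gcc[, , , 1])
      gfavg <- as.numeric(gcc[, , , 2])
      gm <- gm + gfavg / C                 # channel-avg pool backward
      gm[cbind(seq_len(nv), at$argc)] <- gm[cbind(seq_len(nv), at$argc)] + gfmax
      ga4[[i]] <- array(gm, d)
    }
  } else {
    ga4 <- gfeats
  }

  gz4in <- lapply(seq_len(k), function(i) reluBackward(ga4[[i]], cache$a4[[i]]))
  bb4 <- bnBackward(gz4in, cache$b4)
  g$bn4$gamma <- bb4$ggamma; g$bn4$beta <- bb4$gbeta
  ga3 <- vector("list", k)
  for (i in seq_len(k)) {
    cb <- conv3dBackward(cache$a3[[i]], pn$conv4$W, bb4$gxs[[i]])
    g$conv4$W <- g$conv4$W + cb$gW; g$conv4$b <- g$conv4$b + cb$gb
    ga3[[i]] <- cb$gx
  }
  gz3in <- lapply(seq_len(k), function(i) reluBackward(ga3[[i]], cache$a3[[i]]))
  bb3 <- bnBackward(gz3in, cache$b3)
  g$bn3$gamma <- bb3$ggamma; g$bn3$beta <- bb3$gbeta
  gp2 <- vector("list", k)
  for (i in seq_len(k)) {
    cb <- conv3dBackward(cache$p2[[i]], pn$conv3$W, bb3$gxs[[i]])
    g$conv3$W <- g$conv3$W + cb$gW; g$conv3$b <- g$conv3$b + cb$gb
    gp2[[i]] <- cb$gx
  }
  ga2 <- lapply(seq_len(k), function(i)
    maxPool3dBackward(gp2[[i]], cache$plIdx[[i]], dim(cache$a2[[i]])))
  gz2in <- lapply(seq_len(k), function(i) reluBackward(ga2[[i]], cache$a2[[i]]))
  bb2 <- bnBackward(gz2in, cache$b2)
  g$bn2$gamma <- bb2$ggamma; g$bn2$beta <- bb2$gbeta
  ga1 <- vector("list", k)
  for (i in seq_len(k)) {
    cb <- conv3dBackward(cache$a1[[i]], pn$conv2$W, bb2$gxs[[i]])
    g$conv2$W <- g$conv2$W + cb$gW; g$conv2$b <- g$conv2$b + cb$gb
    ga1[[i]] <- cb$gx
  }
  gz1in <- lapply(seq_len(k), function(i) reluBackward(ga1[[i]], cache$a1[[i]]))
  bb1 <- bnBackward(gz1in, cache$b1)
  g$bn1$gamma <- bb1$ggamma; g$bn1$beta <- bb1$gbeta
  for (i in seq_len(k)) {
    cb <- conv3dBackward(cache$x0[[i]], pn$conv1$W, bb1$gxs[[i]])
    g$conv1$W <- g$conv1$W + cb$gW; g$conv1$b <- g$conv1$b + cb$gb
  }
  g
}

# Fixed (untrained) per-patch embedding used by the no_patchnet_cnn
# ablation: 2x2x2 average pooling to a single-channel w^3 map, effect score
# = patch mean intensity.
fixedEmbeddingBag <- function(patches) {
  feats <- lapply(patches, function(p) {
    d <- dim(p) %/% 2L
    y <- array(0, c(d, 1L))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3]))
      y[i, j, l, 1] <- mean(p[2 * i - (1:0), 2 * j - (1:0), 2 * l - (1:0)])
    y
  })
  list(features = feats,
       effect = vapply(patches, mean, numeric(1)),
       attention = lapply(feats, function(f) array(0.5, dim(f)[1:3])))
}
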