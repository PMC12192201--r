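# Low-level layers for the 3D network. Feature maps are numeric arrays with
# dims (d1, d2, d3, C) (channel-last, so each channel slice is contiguous).
# Convolution weights are matrices (Cout x 27*Cin); see convWeightMatrix()
# for the column ordering. Every layer has a forward returning (output,
# cache) and a backward mapping the output gradient to input/parameter
# gradients; training assembles these by hand (no autodiff dependency).

asMap4 <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

#' Convert a 5D kernel array to the packed convolution weight matrix
#'
#' The network stores a 3x3x3 convolution's weights as a `Cout x 27*Cin`
#' matrix. This helper packs a human-readable array with dims
#' `(3, 3, 3, Cin, Cout)` — kernel offsets along x, y, z, then input and
#' output channel — into that matrix. Column index for input channel `c`
#' (0-based) and kernel tap `(a1, a2, a3)` (1-based array indices) is
#' `c*27 + ((a1-1)*3 + (a2-1))*3 + a3`.
#'
#' @param arr numeric array `(3, 3, 3, Cin, Cout)`.
#' @return Matrix `Cout x 27*Cin`.
#' @export
convWeightMatrix <- function(arr) {
  stopifnot(length(dim(arr)) == 5L, all(dim(arr)[1:3] == 3L))
  Cin <- dim(arr)[4]; Cout <- dim(arr)[5]
  W <- matrix(0, Cout, 27 * Cin)
  for (co in seq_len(Cout))
    for (ci in seq_len(Cin))
      for (a1 in 1:3) for (a2 in 1:3) for (a3 in 1:3) {
        col <- (ci - 1) * 27 + ((a1 - 1) * 3 + (a2 - 1)) * 3 + a3
        W[co, col] <- arr[a1, a2, a3, ci, co]
      }
  W
}

#' Same-size 3D convolution (3x3x3 kernel, stride 1, padding 1)
#'
#' @param x numeric array `(d1, d2, d3, Cin)` (a 3D array is treated as one
#'   channel).
#' @param W weight matrix `Cout x 27*Cin` (see [convWeightMatrix()]).
#' @param b numeric(Cout) bias.
#' @return Array `(d1, d2, d3, Cout)`.
#' @export
conv3d <- function(x, W, b) {
  x <- asMap4(x)
  if (!is.double(x)) storage.mode(x) <- "double"
  cpp_conv3d_fwd(x, dim(x), W, b)
}

conv3dBackward <- function(x, W, gy) {
  x <- asMap4(x)
  if (!is.double(x)) storage.mode(x) <- "double"
  if (!is.double(gy)) storage.mode(gy) <- "double"
  cpp_conv3d_bwd(x, dim(x), W, gy)
}

#' 2x2x2 max pooling with stride 2
#'
#' Output dims are `floor(d/2)` per spatial axis; trailing voxels are
#' dropped. Returns the pooled map and the argmax indices needed for the
#' backward pass.
#'
#' @param x numeric array `(d1, d2, d3, C)`.
#' @return list(y, idx).
#' @export
maxPool3d <- function(x) {
  x <- asMap4(x)
  if (!is.double(x)) storage.mode(x) <- "double"
  cpp_maxpool3d_fwd(x, dim(x))
}

maxPool3dBackward <- function(gy, idx, xdim) {
  if (!is.double(gy)) storage.mode(gy) <- "double"
  cpp_maxpool3d_bwd(gy, idx, as.integer(xdim))
}

# --- Batch normalization -----------------------------------------------
# Normalizes per channel over all spatial positions of all items in `xs`
# (a list of (d1,d2,d3,C) arrays — the k instances of one bag form the
# normalization batch). Training mode uses batch statistics and updates
# running moments; inference mode uses running moments only, so evaluation
# is deterministic.

bnForward <- function(xs, bn, training, momentum = 0.1, eps = 1e-5) {
  C <- dim(xs[[1]])[4]
  nv <- prod(dim(xs[[1]])[1:3])
  X <- do.call(rbind, lapply(xs, function(x) matrix(x, nv, C)))
  if (training) {
    mu <- colMeans(X)
    va <- colMeans(X^2) - mu^2           # biased variance
    bn$rm <- (1 - momentum) * bn$rm + momentum * mu
    bn$rv <- (1 - momentum) * bn$rv + momentum * va
  } else {
    mu <- bn$rm; va <- bn$rv
  }
  istd <- 1 / sqrt(va + eps)
  m <- nrow(X)
  xhat <- (X - rep(mu, each = m)) * rep(istd, each = m)
  Y <- xhat * rep(bn$gamma, each = m) + rep(bn$beta, each = m)
  dims <- dim(xs[[1]])
  ys <- lapply(seq_along(xs), function(i)
    array(Y[(i - 1) * nv + seq_len(nv), ], dims))
  list(ys = ys, bn = bn,
       cache = list(xhat = xhat, istd = istd, gamma = bn$gamma, nv = nv,
                    dims = dims, n = length(xs), training = training))
}

bnBackward <- function(gys, cache) {
  nv <- cache$nv; C <- cache$dims[4]
  G <- do.call(rbind, lapply(gys, function(g) matrix(g, nv, C)))
  xhat <- cache$xhat
  ggamma <- colSums(G * xhat)
  gbeta <- colSums(G)
  m <- nrow(G)
  gi <- rep(cache$gamma * cache$istd, each = m)
  GX <- if (cache$training)
    (G - rep(gbeta / m, each = m) - xhat * rep(ggamma / m, each = m)) * gi
  else G * gi
  gxs <- lapply(seq_len(cache$n), function(i)
    array(GX[(i - 1) * nv + seq_len(nv), ], cache$dims))
  list(gxs = gxs, ggamma = ggamma, gbeta = gbeta)
}

reluForward <- function(x) {
  y <- pmax(x, 0)
  attributes(y) <- attributes(x)
  y
}

reluBackward <- function(gy, y) gy * (y > 0)

denseForward <- function(x, W, b) as.numeric(W %*% x + b)

denseBackward <- function(x, W, gy) {
  list(gx = as.numeric(crossprod(W, gy)), gW = tcrossprod(gy, x), gb = gy)
}

softmaxProbs <- function(logits) {
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

newBN <- function(C) list(gamma = rep(1, C), beta = rep(0, C),
                          rm = rep(0, C), rv = rep(1, C))

# He-style init for a 3x3x3 conv, seeded by the caller's RNG state
newConv <- function(Cin, Cout) {
  list(W = matrix(rnorm(Cout * 27 * Cin, sd = sqrt(2 / (27 * Cin))), Cout, 27 * Cin),
       b = rep(0, Cout))
}
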