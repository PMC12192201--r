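# Brute-force oracles and tiny fixtures, independent of the package's
# computation paths.

# dense triple-loop 3x3x3 same-padding convolution
convOracle <- function(x, arr, b) {
  d <- dim(x); Cin <- d[4]; Cout <- dim(arr)[5]
  y <- array(0, c(d[1:3], Cout))
  for (co in 1:Cout) for (i in 1:d[1]) for (j in 1:d[2]) for (l in 1:d[3]) {
    s <- b[co]
    for (ci in 1:Cin) for (a1 in 1:3) for (a2 in 1:3) for (a3 in 1:3) {
      ii <- i + a1 - 2; jj <- j + a2 - 2; ll <- l + a3 - 2
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && ll >= 1 && ll <= d[3])
        s <- s + arr[a1, a2, a3, ci, co] * x[ii, jj, ll, ci]
    }
    y[i, j, l, co] <- s
  }
  y
}

# pairwise Mann-Whitney AUC with ties counted 1/2
aucOracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

confusionOracle <- function(labels, calls) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && calls[i] == 1) tp <- tp + 1L
    if (labels[i] == 0 && calls[i] == 0) tn <- tn + 1L
    if (labels[i] == 0 && calls[i] == 1) fp <- fp + 1L
    if (labels[i] == 1 && calls[i] == 0) fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# a small random bag model plus random patches
tinyModel <- function(k = 2, W = 6, seed = 1, flags = character(0)) {
  newBagModel(k = k, W = W, channels = c(2, 2, 3, 3), attHidden = 2,
              classifierChannels = c(2, 2), flags = flags, seed = seed)
}

randomPatches <- function(k, W, seed = 1) {
  set.seed(seed)
  lapply(seq_len(k), function(i) array(rnorm(W^3), rep(W, 3)))
}

randomBags <- function(n, k, W, seed = 1, sep = 2) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  bags <- lapply(seq_len(n), function(i) {
    patches <- lapply(seq_len(k), function(j)
      array(rnorm(W^3, mean = if (labels[i] == 1 && j == 1) sep else 0), rep(W, 3)))
    new("PatchBag", patches = patches,
        origins = cbind(0L, 0L, as.integer(W * (seq_len(k) - 1))),
        width = as.integer(W), label = labels[i],
        subjectID = sprintf("t%02d", i))
  })
  bags
}

foamidlNs <- asNamespace("foamidl")
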