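test_that("compressAndStack averages channels and preserves bag order", {
  F1 <- array(2, c(2, 2, 2, 3))   # both/all channels constant
  G <- compressAndStack(list(F1))
  expect_equal(G, array(2, c(2, 2, 2, 1)))

  set.seed(8)
  feats <- lapply(1:4, function(i) array(rnorm(8 * 3), c(2, 2, 2, 3)))
  G4 <- compressAndStack(feats)
  expect_equal(dim(G4), c(2L, 2L, 2L, 4L))
  for (i in 1:4) {
    av <- apply(feats[[i]], 1:3, mean)
    expect_equal(G4[, , , i], av, tolerance = 1e-12)
  }
  expect_error(compressAndStack(list(F1, array(1, c(3, 3, 3, 3)))), "share one shape")
})

test_that("descriptorAttention applies the shared per-patch scalar MLP", {
  set.seed(9)
  G <- array(rnorm(8 * 3), c(2, 2, 2, 3))
  # zero parameters -> both outputs collapse to the b1 broadcast
  z <- list(w0 = rep(0, 4), b0 = rep(0, 4), w1 = rep(0, 4), b1 = 0.4)
  da <- descriptorAttention(G, z)
  expect_equal(da$Aaverage, rep(0.4, 3))
  expect_equal(da$Amax, rep(0.4, 3))

  # constant patch map: GAP = GMP, so the two paths agree on that patch
  Gc <- G; Gc[, , , 2] <- 1.5
  p <- list(w0 = rnorm(4), b0 = rnorm(4), w1 = rnorm(4), b1 = rnorm(1))
  dc <- descriptorAttention(Gc, p)
  expect_equal(dc$Aaverage[2], dc$Amax[2], tolerance = 1e-12)

  # dense oracle
  mlp <- function(x) sum(p$w1 * pmax(p$w0 * x + p$b0, 0)) + p$b1
  m <- matrix(G, 8, 3)
  expect_equal(da2 <- descriptorAttention(G, p)$Aaverage,
               vapply(colMeans(m), mlp, numeric(1)), tolerance = 1e-12)
  expect_equal(descriptorAttention(G, p)$Amax,
               vapply(apply(m, 2, max), mlp, numeric(1)), tolerance = 1e-12)
})

test_that("fuseAttention is the sigmoid of the element-wise sum", {
  expect_equal(fuseAttention(rep(0, 3), rep(0, 3), rep(0, 3)), rep(0.5, 3))
  # saturation
  expect_equal(fuseAttention(50, 0, 0), 1, tolerance = 1e-8)
  set.seed(10)
  a <- rnorm(5); b <- rnorm(5); e <- rnorm(5)
  expect_equal(fuseAttention(a, b, e), 1 / (1 + exp(-(a + b + e))), tolerance = 1e-14)
  expect_error(fuseAttention(a, b, rnorm(4)), "equal length")
})

test_that("applyPatchAttention scales patch maps and honors limits", {
  set.seed(11)
  G <- array(rnorm(8 * 3), c(2, 2, 2, 3))
  expect_equal(applyPatchAttention(G, rep(1, 3)), G)
  z <- applyPatchAttention(G, c(1, 0, 1))
  expect_true(all(z[, , , 2] == 0))
  w <- runif(3)
  out <- applyPatchAttention(G, w)
  for (i in 1:3) expect_equal(out[, , , i], G[, , , i] * w[i], tolerance = 1e-12)
  expect_error(applyPatchAttention(G, rep(1, 4)), "does not match")
})

test_that("amidlPool composes the stages and reduces correctly for k = 1", {
  set.seed(12)
  p <- list(w0 = rnorm(4), b0 = rnorm(4), w1 = rnorm(4), b1 = rnorm(1))
  f1 <- list(array(rnorm(8 * 2), c(2, 2, 2, 2)))
  out <- amidlPool(f1, effect = 0.3, params = p)
  expect_length(out$attention, 1)
  G <- compressAndStack(f1)
  expect_equal(out$global, G * out$attention, tolerance = 1e-12)

  # zero parameters, zero effect -> all weights 0.5, halved maps
  z <- list(w0 = rep(0, 4), b0 = rep(0, 4), w1 = rep(0, 4), b1 = 0)
  feats <- lapply(1:3, function(i) array(rnorm(8 * 2), c(2, 2, 2, 2)))
  oz <- amidlPool(feats, effect = rep(0, 3), params = z)
  expect_equal(oz$attention, rep(0.5, 3))
  expect_equal(oz$global, compressAndStack(feats) * 0.5, tolerance = 1e-12)
})

test_that("amidlPool is permutation equivariant", {
  set.seed(13)
  p <- list(w0 = rnorm(4), b0 = rnorm(4), w1 = rnorm(4), b1 = rnorm(1))
  feats <- lapply(1:5, function(i) array(rnorm(8 * 2), c(2, 2, 2, 2)))
  eff <- rnorm(5)
  base <- amidlPool(feats, eff, p)
  perm <- c(3, 5, 1, 2, 4)
  permd <- amidlPool(feats[perm], eff[perm], p)
  expect_equal(permd$attention, base$attention[perm], tolerance = 1e-12)
  expect_equal(permd$global, base$global[, , , perm], tolerance = 1e-12)
})

test_that("attention weight is strictly increasing in the effect score", {
  set.seed(14)
  p <- list(w0 = rnorm(4), b0 = rnorm(4), w1 = rnorm(4), b1 = rnorm(1))
  feats <- lapply(1:3, function(i) array(rnorm(8 * 2), c(2, 2, 2, 2)))
  eff <- c(0, 0, 0)
  w0 <- amidlPool(feats, eff, p)$attention
  for (delta in c(0.1, 0.5, 2)) {
    w1 <- amidlPool(feats, eff + c(delta, 0, 0), p)$attention
    expect_gt(w1[1], w0[1])
    expect_equal(w1[-1], w0[-1], tolerance = 1e-12)
  }
})
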