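makeGroups <- function(n, shape = c(6, 6, 6), seed = 1, shiftAt = NULL, shift = 0) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x <- array(rnorm(prod(shape)), shape)
    if (!is.null(shiftAt))
      x[shiftAt[1] + 1:3, shiftAt[2] + 1:3, shiftAt[3] + 1:3] <-
        x[shiftAt[1] + 1:3, shiftAt[2] + 1:3, shiftAt[3] + 1:3] + shift
    Volume3D(x, subjectID = sprintf("g%d", i))
  })
}

test_that("null groups give ~5% of locations below 0.05", {
  # aggregate over several seeded null cohorts for a stable rate
  hits <- 0; total <- 0
  for (s in 1:6) {
    ga <- makeGroups(20, shape = c(12, 12, 12), seed = 100 + s)
    gb <- makeGroups(20, shape = c(12, 12, 12), seed = 200 + s)
    m <- groupTTestMap(ga, gb, W = 4)
    hits <- hits + sum(rawPValues(m) < 0.05)
    total <- total + length(rawPValues(m))
  }
  expect_gt(hits / total, 0.01)
  expect_lt(hits / total, 0.11)
})

test_that("a strongly shifted location attains the minimum p-value", {
  ga <- makeGroups(10, seed = 5, shiftAt = c(3, 0, 3), shift = 10)
  gb <- makeGroups(10, seed = 6)
  m <- groupTTestMap(ga, gb, W = 3)
  best <- which.min(rawPValues(m))
  expect_equal(patchOrigins(m)[best, ], c(3L, 0L, 3L))
  expect_equal(normScores(m)[best], 0)
})

test_that("degenerate constant groups give p = 1 with a warning", {
  ga <- lapply(1:3, function(i) Volume3D(array(2, c(4, 4, 4)), subjectID = "a"))
  gb <- lapply(1:3, function(i) Volume3D(array(2, c(4, 4, 4)), subjectID = "b"))
  expect_warning(m <- groupTTestMap(ga, gb, W = 2), "zero within-group variance")
  expect_true(all(rawPValues(m) == 1))
})

test_that("welch p-values agree with stats::t.test", {
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(7, sd = runif(1, 0.5, 2)); b <- rnorm(9, mean = runif(1, -1, 1))
    expect_equal(foamidlNs$welchP(matrix(a), matrix(b)),
                 t.test(a, b)$p.value, tolerance = 1e-12)
  }
})

test_that("voxel-wise statistic mode produces a valid map", {
  ga <- makeGroups(5, seed = 21, shiftAt = c(0, 0, 0), shift = 8)
  gb <- makeGroups(5, seed = 22)
  m <- groupTTestMap(ga, gb, W = 3, statistic = "voxel_wise")
  expect_true(all(rawPValues(m) >= 0 & rawPValues(m) <= 1))
  expect_equal(patchOrigins(m)[which.min(rawPValues(m)), ], c(0L, 0L, 0L))
})

test_that("normalizePValues is the min-max affine map with degenerate rule", {
  mk <- function(p) new("PValueMap",
                        origins = cbind(0L, 0L, as.integer(3 * (seq_along(p) - 1))),
                        width = 3L, pRaw = p, pNorm = rep(NA_real_, length(p)),
                        groupSizes = c(2L, 2L), statistic = "patch_mean")
  expect_equal(normScores(normalizePValues(mk(c(0.2, 0.5, 0.8)))), c(0, 0.5, 1))
  expect_equal(normScores(normalizePValues(mk(rep(0.3, 4)))), rep(0, 4))
  expect_equal(normScores(normalizePValues(mk(c(0.01, 0.04, 0.10)))),
               c(0, 1 / 3, 1))
  # order preservation on random raw values
  set.seed(2)
  p <- runif(50)
  ns <- normScores(normalizePValues(mk(p)))
  expect_equal(order(ns), order(p))
})

test_that("selectBagLocations sorts ascending with lexicographic ties", {
  o <- rbind(c(0L, 0L, 3L), c(0L, 0L, 0L), c(3L, 0L, 0L))
  m <- new("PValueMap", origins = o, width = 3L,
           pRaw = c(0.5, 0.1, 0.2), pNorm = c(1, 0, 0.25),
           groupSizes = c(2L, 2L), statistic = "patch_mean")
  sel <- selectBagLocations(m, 2)
  expect_equal(patchOrigins(sel), rbind(c(0L, 0L, 0L), c(3L, 0L, 0L)))

  # tie: two zero scores -> lexicographically smaller coord first
  m2 <- new("PValueMap", origins = o, width = 3L,
            pRaw = c(0.1, 0.1, 0.9), pNorm = c(0, 0, 1),
            groupSizes = c(2L, 2L), statistic = "patch_mean")
  expect_equal(patchOrigins(selectBagLocations(m2, 2)),
               rbind(c(0L, 0L, 0L), c(0L, 0L, 3L)))

  # insertion-order invariance
  perm <- c(3, 1, 2)
  m3 <- new("PValueMap", origins = o[perm, ], width = 3L,
            pRaw = c(0.5, 0.1, 0.2)[perm], pNorm = c(1, 0, 0.25)[perm],
            groupSizes = c(2L, 2L), statistic = "patch_mean")
  expect_equal(patchOrigins(selectBagLocations(m3, 3)),
               patchOrigins(selectBagLocations(m, 3)))

  expect_error(selectBagLocations(m, 4), "between 1 and")
})

test_that("buildBag extracts spec patches in identical order across subjects", {
  set.seed(4)
  v1 <- Volume3D(array(rnorm(216), c(6, 6, 6)), subjectID = "s1")
  v2 <- Volume3D(array(rnorm(216), c(6, 6, 6)), subjectID = "s2")
  spec <- new("PatchSet", origins = rbind(c(3L, 0L, 0L), c(0L, 3L, 3L)), width = 3L)
  b1 <- buildBag(v1, spec, label = 1)
  b2 <- buildBag(v2, spec)
  expect_identical(patchOrigins(b1), patchOrigins(b2))
  expect_equal(bagPatches(b1)[[1]], extractPatch(v1, c(3, 0, 0), 3))
  expect_equal(bagLabel(b1), 1L)
  expect_true(is.na(bagLabel(b2)))
  spec1 <- new("PatchSet", origins = matrix(0L, 1, 3), width = 3L)
  expect_equal(bagPatches(buildBag(v1, spec1))[[1]], extractPatch(v1, c(0, 0, 0), 3))
})

test_that("p-value map and bag spec survive the CSV round trip", {
  ga <- makeGroups(4, seed = 31); gb <- makeGroups(4, seed = 32)
  m <- groupTTestMap(ga, gb, W = 3)
  f <- tempfile(fileext = ".csv")
  writePValueMap(m, f)
  m2 <- readPValueMap(f, groupSizes = c(4L, 4L))
  expect_equal(patchOrigins(m2), patchOrigins(m))
  expect_equal(rawPValues(m2), rawPValues(m))
  sel <- selectBagLocations(m, 3)
  f2 <- tempfile(fileext = ".csv")
  writeBagSpec(sel, f2)
  expect_equal(patchOrigins(readBagSpec(f2)), patchOrigins(sel))
})

test_that("lesion recovery: injected lesion ranks first across seeded cohorts", {
  hits <- 0
  for (s in 1:10) {
    cfg <- syntheticCohortConfig(shape = c(24, 24, 24), nPerGroup = 15,
                                 lesions = list(list(origin = c(6, 6, 6), width = 6)),
                                 effectSize = 1.5, seed = 400 + s)
    coh <- generateCohort(cfg)
    m <- groupTTestMap(coh$volumes[coh$labels == 0], coh$volumes[coh$labels == 1], W = 6)
    top <- patchOrigins(selectBagLocations(m, 1))
    hits <- hits + all(top == c(6L, 6L, 6L))
  }
  expect_gte(hits, 9)
})
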