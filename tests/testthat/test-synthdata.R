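smallCfg <- function(nPerGroup = 10, ...) {
  syntheticCohortConfig(shape = c(24, 24, 24), nPerGroup = nPerGroup,
                        lesions = list(list(origin = c(6, 6, 6), width = 6)),
                        smoothness = 2, ...)
}

test_that("cohorts are reproducible from the seed", {
  c1 <- generateCohort(smallCfg(seed = 7))
  c2 <- generateCohort(smallCfg(seed = 7))
  expect_identical(lapply(c1$volumes, volData), lapply(c2$volumes, volData))
  expect_identical(c1$labels, c2$labels)
  c3 <- generateCohort(smallCfg(seed = 8))
  expect_false(identical(volData(c1$volumes[[1]]), volData(c3$volumes[[1]])))
})

test_that("config validation rejects out-of-volume lesions", {
  expect_error(syntheticCohortConfig(shape = c(16, 16, 16),
                                     lesions = list(list(origin = c(10, 10, 10), width = 12))),
               "outside the volume")
  expect_error(syntheticCohortConfig(effectSize = -1), "effectSize")
})

test_that("null cohorts (d = 0) give uniform p-values", {
  cfg <- syntheticCohortConfig(shape = c(36, 36, 36), nPerGroup = 40,
                               lesions = list(list(origin = c(12, 12, 12), width = 12)),
                               effectSize = 0, smoothness = 3, seed = 9)
  coh <- generateCohort(cfg)
  m <- groupTTestMap(coh$volumes[coh$labels == 0], coh$volumes[coh$labels == 1], W = 6)
  ks <- suppressWarnings(ks.test(rawPValues(m), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a huge effect pins the lesion to the map minimum", {
  cfg <- smallCfg(effectSize = 10, seed = 10)
  coh <- generateCohort(cfg)
  m <- groupTTestMap(coh$volumes[coh$labels == 0], coh$volumes[coh$labels == 1], W = 6)
  expect_equal(patchOrigins(m)[which.min(rawPValues(m)), ], c(6L, 6L, 6L))
})

test_that("realized standardized effect matches the configured d", {
  cfg <- syntheticCohortConfig(shape = c(24, 24, 24), nPerGroup = 50,
                               lesions = list(list(origin = c(6, 6, 6), width = 6)),
                               effectSize = 1.5, smoothness = 2, seed = 11)
  coh <- generateCohort(cfg)
  lesionVals <- function(v) as.numeric(extractPatch(v, c(6, 6, 6), 6))
  g0 <- sapply(coh$volumes[coh$labels == 0], function(v) mean(lesionVals(v)))
  g1 <- sapply(coh$volumes[coh$labels == 1], function(v) mean(lesionVals(v)))
  # voxel-level SD within a subject's lesion after removing the shared base:
  # use the pooled per-voxel SD across subjects
  A <- sapply(coh$volumes[coh$labels == 0], lesionVals)
  B <- sapply(coh$volumes[coh$labels == 1], lesionVals)
  pooledSd <- sqrt((mean(apply(A, 1, var)) + mean(apply(B, 1, var))) / 2)
  d <- (mean(g0) - mean(g1)) / pooledSd      # reduction => positive
  expect_lt(abs(d - 1.5) / 1.5, 0.15)
})

test_that("no leakage outside lesions", {
  cfg <- syntheticCohortConfig(shape = c(24, 24, 24), nPerGroup = 60,
                               lesions = list(list(origin = c(0, 0, 0), width = 6)),
                               effectSize = 3, smoothness = 2, seed = 12)
  coh <- generateCohort(cfg)
  # mean over a far-away cube: group means differ by < 3 standard errors
  far <- function(v) mean(extractPatch(v, c(12, 12, 12), 6))
  a <- sapply(coh$volumes[coh$labels == 0], far)
  b <- sapply(coh$volumes[coh$labels == 1], far)
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})

test_that("written cohorts round trip through NIfTI + manifest", {
  coh <- generateCohort(smallCfg(nPerGroup = 3, seed = 13))
  d <- tempfile()
  manifest <- writeCohort(coh$volumes, coh$labels, d, groundTruth = coh$groundTruth)
  m <- readManifest(manifest)
  expect_equal(nrow(m), 6)
  expect_true(all(m$label %in% c(0, 1)))
  v <- readVolume(m$path[4])
  expect_equal(volData(v), volData(coh$volumes[[4]]), tolerance = 1e-12)
  gt <- readBagSpec(file.path(d, "ground_truth.csv"))
  expect_equal(patchOrigins(gt), patchOrigins(coh$groundTruth))
})
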