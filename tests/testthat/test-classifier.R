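test_that("global classifier outputs normalized, deterministic probabilities", {
  set.seed(15)
  model <- tinyModel(k = 3, W = 6, seed = 31)
  G <- array(rnorm(27 * 3), c(3, 3, 3, 3))
  p1 <- globalClassifierForward(G, model)
  p2 <- globalClassifierForward(G, model)
  expect_equal(sum(p1$probs), 1, tolerance = 1e-12)
  expect_identical(p1$probs, p2$probs)
  # zero final layer -> symmetric logits
  model@classifier$fc$W[] <- 0
  model@classifier$fc$b[] <- 0
  expect_equal(globalClassifierForward(G, model)$probs, c(0.5, 0.5))
  expect_error(globalClassifierForward(array(0, c(3, 3, 3, 5)), model), "k = 3")
})

test_that("bagForward composes the pipeline and is deterministic", {
  model <- newBagModel(k = 5, W = 25, seed = 7)
  set.seed(16)
  patches <- randomPatches(5, 25, seed = 41)
  bag <- new("PatchBag", patches = patches,
             origins = cbind(as.integer(25 * (0:4)), 0L, 0L), width = 25L,
             label = 1L, subjectID = "s")
  pr <- bagForward(bag, model)
  expect_equal(sum(pr$probs), 1, tolerance = 1e-12)
  expect_length(pr$attention, 5)
  expect_true(all(pr$attention > 0 & pr$attention < 1))
  pr2 <- bagForward(bag, model)
  expect_identical(pr$probs, pr2$probs)
})

test_that("cross entropy loss follows the closed forms", {
  mk <- function(p) list(probs = c(1 - p, p))
  expect_equal(crossEntropyLoss(list(mk(1)), 1L), 0)
  expect_equal(crossEntropyLoss(list(mk(0.5)), 1L), log(2), tolerance = 1e-12)
  expect_equal(crossEntropyLoss(list(mk(1), mk(0.5)), c(1L, 1L)), log(2) / 2,
               tolerance = 1e-12)
  expect_error(crossEntropyLoss(list(), integer(0)), "non-empty")
  expect_error(crossEntropyLoss(list(mk(0.5)), 2L), "0 or 1")
})

test_that("ablation flags build the reduced models and they all run", {
  expect_error(newBagModel(k = 2, W = 6, flags = "no_dropout"), "unknown ablation")
  full <- ablationVariant(character(0), k = 2, W = 6, channels = c(2, 2, 2, 2),
                          classifierChannels = c(2, 2), seed = 5)
  expect_false(any(unlist(full@config$flags)))

  bags <- randomBags(6, k = 2, W = 6, seed = 42)
  for (fl in list("no_attention", "no_patchnet_cnn",
                  c("no_patchnet_cnn", "no_attention", "no_fssa"))) {
    m <- ablationVariant(fl, k = 2, W = 6, channels = c(2, 2, 2, 2),
                         classifierChannels = c(2, 2), seed = 5)
    tr <- trainBagModel(m, bags, bags, lr = 1e-3, epochs = 2, batchSize = 3, seed = 1)
    ev <- evaluateBags(tr$model, bags)
    expect_true(is.finite(ev$acc))
    if ("no_attention" %in% fl) {
      pr <- bagForward(bags[[1]], tr$model)
      expect_equal(pr$attention, rep(0.5, 2))
    }
  }
})

test_that("training is reproducible, no-op at zero lr, and can overfit", {
  bags <- randomBags(10, k = 2, W = 6, seed = 43, sep = 1.5)
  model <- tinyModel(k = 2, W = 6, seed = 6)

  tr0 <- trainBagModel(model, bags, bags, lr = 0, epochs = 2, batchSize = 5, seed = 2)
  expect_equal(foamidlNs$paramsToVector(tr0$model),
               foamidlNs$paramsToVector(model), tolerance = 1e-14)

  trA <- trainBagModel(model, bags, bags, lr = 1e-3, epochs = 3, batchSize = 5, seed = 2)
  trB <- trainBagModel(model, bags, bags, lr = 1e-3, epochs = 3, batchSize = 5, seed = 2)
  expect_identical(trA$history, trB$history)

  tr <- trainBagModel(model, bags, bags, lr = 1e-3, epochs = 200, batchSize = 5,
                      patience = 200, seed = 3)
  expect_lt(tail(tr$history$train_loss, 1), 0.05)
})

test_that("full-batch descent at small lr does not increase the loss", {
  bags <- randomBags(6, k = 2, W = 6, seed = 44, sep = 1.5)
  model <- tinyModel(k = 2, W = 6, seed = 8)
  tr <- trainBagModel(model, bags, bags, lr = 1e-4, epochs = 12,
                      batchSize = length(bags), patience = 20,
                      optimizer = "sgd", seed = 4)
  expect_true(all(diff(tr$history$train_loss) <= 1e-8))
})

test_that("training aborts with a diagnostic on unlabelled bags", {
  bags <- randomBags(4, k = 2, W = 6, seed = 45)
  bags[[2]]@label <- NA_integer_
  model <- tinyModel(k = 2, W = 6)
  expect_error(trainBagModel(model, bags, bags, epochs = 1), "labelled")
})
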