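test_that("the filter/spatial schedule doubles filters and halves sides per stage", {
  nc <- netConfig(depth = 2, baseFilters = 8, inSize = 64)
  plan <- unetStagePlan(nc)
  expect_equal(plan$filters, c(8, 16))
  expect_equal(plan$side, c(64, 32))
  m <- buildUnet(nc, seed = 1)
  # introspect actual weight shapes: enc1 conv2 maps 8 -> 8, enc2 maps 8 -> 16,
  # the up-convolution halves 16 -> 8
  expect_equal(dim(m@params[["enc1.c2.w"]]), c(9 * 8, 8))
  expect_equal(dim(m@params[["enc2.c1.w"]]), c(9 * 8, 16))
  expect_equal(dim(m@params[["dec1.up.w"]]), c(16, 4 * 8))
  nc3 <- netConfig(depth = 3, baseFilters = 4, inSize = 64)
  expect_equal(unetStagePlan(nc3)$filters, c(4, 8, 16))
  expect_error(netConfig(depth = 3, inSize = 100), "divisible")
})

test_that("a forward pass honors the shape and range contract", {
  nc <- netConfig(depth = 2, baseFilters = 4, inSize = 64)
  m <- buildUnet(nc, seed = 2)
  x <- array(runif(64 * 64), c(64, 64, 1))
  fw <- bcmseg:::unetForward(m, x, 1)
  expect_equal(dim(fw$prob), c(64, 64, 1))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
})

test_that("zero head weights give a constant 0.5 probability map", {
  nc <- netConfig(depth = 2, baseFilters = 4, inSize = 32)
  m <- buildUnet(nc, seed = 3)
  m@params[["head.w"]][] <- 0
  m@params[["head.b"]] <- 0
  fw <- bcmseg:::unetForward(m, array(runif(32 * 32), c(32, 32, 1)), 1)
  expect_equal(as.numeric(fw$prob), rep(0.5, 32 * 32))
})

test_that("backpropagation matches finite differences", {
  nc <- netConfig(depth = 2, baseFilters = 2, inSize = 8)
  m <- buildUnet(nc, seed = 7)
  B <- 2
  withr::with_seed(42, {
    x <- array(runif(8 * 8 * B), c(8, 8, B))
    y <- array(rbinom(8 * 8 * B, 1, 0.3), c(8, 8, B))
    fw <- bcmseg:::unetForward(m, x, B, keepCache = TRUE)
    ls <- bcmseg:::.bceLoss(fw$prob, y)
    g <- bcmseg:::unetBackward(m, fw$cache, ls$grad, B)
    lossAt <- function(model) {
      f <- bcmseg:::unetForward(model, x, B)
      bcmseg:::.bceLoss(f$prob, y)$loss
    }
    eps <- 1e-5
    for (nm in names(m@params)) {
      p <- m@params[[nm]]
      for (i in sample(length(p), min(3, length(p)))) {
        m2 <- m; m2@params[[nm]][i] <- p[i] + eps
        m3 <- m; m3@params[[nm]][i] <- p[i] - eps
        fd <- (lossAt(m2) - lossAt(m3)) / (2 * eps)
        expect_equal(g[[nm]][i], fd, tolerance = 1e-4,
                     label = sprintf("grad %s[%d]", nm, i))
      }
    }
  })
})

test_that("a zero learning rate leaves parameters at their initialization", {
  split <- easySplit()
  net <- netConfig(depth = 2, baseFilters = 2, inSize = 32)
  cfg <- trainConfig(batchScheme("P50"), steps = 1, lr = 0, seed = 11)
  m <- trainModel(split, cfg, net)
  init <- buildUnet(net, seed = 11)  # trainModel seeds the same stream
  expect_equal(m@params, init@params)
})

test_that("training is reproducible: identical seeds give identical loss traces", {
  split <- easySplit()
  net <- netConfig(depth = 2, baseFilters = 2, inSize = 32)
  cfg <- trainConfig(batchScheme("P50"), steps = 5, lr = 1e-3, seed = 13)
  m1 <- trainModel(split, cfg, net)
  m2 <- trainModel(split, cfg, net)
  expect_identical(lossTrace(m1), lossTrace(m2))
  expect_identical(m1@params, m2@params)
})

test_that("a short training solves the easily separable phantom task", {
  m <- easyTrainedModel()
  tab <- evaluateCases(m, testCases(easySplit()))
  mt <- computeMetrics(countOutcomes(tab))
  expect_gte(mt$f1, 0.9)
  # loss trend over 100-step windows is non-increasing (trend, not monotone)
  lt <- lossTrace(m)
  w <- vapply(split(lt, ceiling(seq_along(lt) / 100)), mean, 0)
  expect_true(all(diff(w) < 0.02))
  expect_lt(w[length(w)], w[1] / 2)
})

test_that("prediction respects threshold semantics and original resolution", {
  m <- easyTrainedModel()
  pc <- testCases(easySplit())[[1]]
  img <- normalizeRaster(pc@raster)
  pm <- predictMask(m, img, threshold = 0)
  expect_equal(dim(pm$mask), dim(img@pixels))  # back at original resolution
  expect_true(all(pm$mask == 1))               # threshold 0 -> all foreground
  pmHi <- predictMask(m, img, threshold = 1 + 1e-9)
  expect_true(all(pmHi$mask == 0))
  expect_true(all(pm$prob >= 0 & pm$prob <= 1))
})

test_that("a synthetic model emitting the ground truth reproduces the mask", {
  # plumbing identity via the fixed-threshold segmenter on a noise-free phantom
  cfg <- phantomConfig(imageSize = 64, noiseSd = 0, blobContrast = 0.7)
  withr::with_seed(5, pc <- generatePhantomCase(cfg, "lung_opacity"))
  seg <- thresholdSegmenter(0.25 + 0.7 / 2)
  pm <- predictMask(seg, pc@raster)
  expect_identical(pm$mask, pc@mask)
})
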