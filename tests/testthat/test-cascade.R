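test_that("a freshly built cascade reproduces the zero-filled input exactly", {
  n <- 32
  truth <- randomComplex(n, 41)
  mask <- makeSamplingMask(c(n, n), 4, 0.1, 2)
  km <- imgValues(forwardFFT(complexImage(truth)))
  km[!maskKeep(mask)] <- 0 + 0i
  model <- buildCascadeModel(seed = 1)   # zero-initialised fusion maps
  out <- cascadeForward(model, km, mask, record = TRUE)
  zf <- imgValues(zeroFilled(km, mask))
  expect_lt(max(Mod(imgValues(out$image) - zf)), 1e-12)
  expect_lt(max(Mod(out$input - zf)), 1e-12)
})

test_that("hard data consistency holds after every stage and at the output", {
  n <- 32
  truth <- randomComplex(n, 42)
  mask <- makeSamplingMask(c(n, n), 4, 0.1, 3)
  keep <- maskKeep(mask)
  km <- imgValues(forwardFFT(complexImage(truth)))
  km[!keep] <- 0 + 0i
  model <- randomizeModel(buildCascadeModel(seed = 2), seed = 7)
  rec <- cascadeForward(model, km, mask, record = TRUE)
  for (s in 1:5)
    expect_lt(max(Mod(rec$stageK[[s]][keep] - km[keep])), 1e-12)
  kOut <- imgValues(forwardFFT(rec$image))
  expect_lt(max(Mod(kOut[keep] - km[keep])), 1e-10)
})

test_that("stage outputs decompose as input plus residual branch (telescoping)", {
  n <- 32
  truth <- randomComplex(n, 43)
  mask <- makeSamplingMask(c(n, n), 3, 0.1, 4)
  km <- imgValues(forwardFFT(complexImage(truth)))
  km[!maskKeep(mask)] <- 0 + 0i
  model <- randomizeModel(buildCascadeModel(fusion = "identity", seed = 3),
                          seed = 11)
  rec <- cascadeForward(model, km, mask, record = TRUE)
  # independent summation oracle: stage-5 image = input + sum of residuals
  summed <- rec$input + Reduce(`+`, rec$residuals)
  relErr <- max(Mod(rec$stageImg[[5]] - summed)) / max(Mod(summed))
  expect_lt(relErr, 1e-5)
  # per-stage additivity is exact
  img <- rec$input
  for (s in 1:5) {
    img <- img + rec$residuals[[s]]
    expect_lt(max(Mod(rec$stageImg[[s]] - img)), 1e-12)
  }
})

test_that("full sampling with hard consistency recovers the truth exactly", {
  n <- 24
  truth <- randomComplex(n, 44)
  mask <- makeSamplingMask(c(n, n), 1, 0.1, 5)   # acceleration 1
  km <- imgValues(forwardFFT(complexImage(truth)))
  model <- randomizeModel(buildCascadeModel(seed = 4), seed = 13)
  out <- cascadeForward(model, km, mask)
  expect_lt(max(Mod(imgValues(out) - truth)), 1e-10)
})

test_that("cascade forward is deterministic for a fixed model", {
  n <- 24
  mask <- makeSamplingMask(c(n, n), 3, 0.1, 6)
  km <- imgValues(forwardFFT(complexImage(randomComplex(n, 45))))
  km[!maskKeep(mask)] <- 0 + 0i
  model <- randomizeModel(buildCascadeModel(seed = 5), seed = 17)
  a <- cascadeForward(model, km, mask)
  b <- cascadeForward(model, km, mask)
  expect_identical(imgValues(a), imgValues(b))
  expect_identical(buildCascadeModel(seed = 9)@stages,
                   buildCascadeModel(seed = 9)@stages)
})

test_that("residual gradients flow: identity path passes gradients unchanged", {
  model <- buildCascadeModel(seed = 6)
  gf <- gradientFlowCheck(model, shape = c(16L, 16L), seed = 2)
  expect_lt(gf$zeroed_gap, 1e-6)
  expect_gt(gf$input_grad_norm, 0)
  expect_true(gf$pass)
  # random weights also keep a non-vanishing input gradient
  gfr <- gradientFlowCheck(randomizeModel(model, seed = 19), c(16L, 16L), 3)
  expect_gt(gfr$input_grad_norm, 0)
})

test_that("training is seeded, frozen at lr 0, and overfits a tiny set", {
  n <- 24
  truth <- randomComplex(n, 46)
  mask <- makeSamplingMask(c(n, n), 2, 0.1, 7)
  km <- imgValues(forwardFFT(complexImage(truth)))
  km[!maskKeep(mask)] <- 0 + 0i
  sample1 <- list(kMeas = km, mask = mask, target = truth)
  model <- buildCascadeModel(stageConfig(n_conv_layers = 2, n_channels = 4),
                             seed = 7)

  # lr = 0: parameters unchanged, loss constant
  frozen <- trainCascade(model, list(sample1),
                         trainConfig(learning_rate = 0, epochs = 3, seed = 1))
  expect_identical(frozen$model@stages, model@stages)
  expect_equal(length(unique(round(frozen$history, 12))), 1L)

  # same seed twice: identical loss curves
  cfg <- trainConfig(learning_rate = 1e-3, epochs = 3, seed = 5)
  h1 <- trainCascade(model, list(sample1), cfg)$history
  h2 <- trainCascade(model, list(sample1), cfg)$history
  expect_identical(h1, h2)

  # enough epochs on one repeated sample drives the loss below 10% of start
  fit <- trainCascade(model, list(sample1, sample1),
                      trainConfig(learning_rate = 5e-3, epochs = 120,
                                  batch_size = 2, seed = 2))
  expect_lt(utils::tail(fit$history, 1), 0.1 * fit$history[1])
})

test_that("image-quality metrics behave at their boundary cases", {
  x <- Mod(randomComplex(16, 47))
  expect_identical(psnr(x, x), Inf)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  z <- matrix(0, 16, 16)
  p0 <- psnr(z, x)
  expect_true(is.finite(p0))
  expect_equal(p0, 20 * log10(max(x) / sqrt(mean(x^2))))
  expect_error(evaluateRecon(buildCascadeModel(seed = 1), list()), "empty")
})
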