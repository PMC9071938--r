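test_that("homodyne correction removes low-frequency phase", {
  mag <- smoothMagnitude(64)
  dim(mag) <- c(64, 64, 1)

  # constant phase is pure low-frequency: corrected phase vanishes
  pair <- new("MagnitudePhasePair", magnitude = mag,
              phase = array(0.8, dim(mag)), spacing = c(1, 1, 1))
  expect_lt(max(abs(highpassPhase(pair, 32))), 1e-6)

  # slow linear ramp: residual at least 10x smaller than the input
  ramp <- array(rep(seq(-0.4, 0.4, length.out = 64), each = 64), dim(mag))
  pairR <- new("MagnitudePhasePair", magnitude = mag, phase = ramp,
               spacing = c(1, 1, 1))
  corr <- highpassPhase(pairR, 32)
  inner <- 17:48   # interior, away from wrap-around edges of the ramp
  expect_lt(mean(abs(corr[inner, inner, 1])),
            mean(abs(ramp[inner, inner, 1])) / 10)

  # a compact phase defect survives with its sign and >= 50% amplitude
  defect <- array(0, dim(mag))
  defect[32, 32, 1] <- -1
  pairD <- new("MagnitudePhasePair", magnitude = mag, phase = defect,
               spacing = c(1, 1, 1))
  corrD <- highpassPhase(pairD, 32)
  expect_lt(corrD[32, 32, 1], -0.5)

  expect_error(highpassPhase(pair, 128), "larger")
  expect_warning(highpassPhase(pair, 16), "non-standard")
})

test_that("negative-phase mask follows its piecewise definition", {
  phi <- array(c(0, -pi, -pi / 2, 0.5, -pi / 4), c(5, 1, 1))
  m1 <- negativePhaseMask(phi, m = 1)
  expect_equal(imgValues(m1)[1:4], c(1, 0, 0.5, 1))
  m4 <- negativePhaseMask(phi, m = 4)
  expect_equal(imgValues(m4)[3], 0.0625)
  expect_equal(imgValues(m4)[2], 0)

  # weights stay in [0,1] for arbitrary wrapped phase
  set.seed(9)
  w <- imgValues(negativePhaseMask(array(runif(1000, -pi, pi - 1e-9),
                                         c(10, 10, 10)), 4))
  expect_true(all(w >= 0 & w <= 1))
})

test_that("SWI composition never exceeds the magnitude", {
  s <- makePhantom(phantomSpec(
    cmb_specs = list(list(center = c(32, 32, 16), diameter = 5,
                          contrast = 1)), seed = 4))
  pair <- magnitudePhase(s)
  phi <- highpassPhase(pair, 64)

  neutral <- composeSWI(pair, negativePhaseMask(phi, m = 0))
  expect_equal(imgValues(neutral), pair@magnitude)

  zeroMask <- new("PhaseMask", weights = array(0, dim(phi)), m = 1)
  expect_true(all(imgValues(composeSWI(pair, zeroMask)) == 0))

  swi <- composeSWI(pair, negativePhaseMask(phi, m = 4))
  expect_true(all(imgValues(swi) <= pair@magnitude + 1e-12))

  # the implanted microbleed darkens relative to the magnitude image
  g <- SWIcascade:::.mmGrids(dim(phi), s@spacing)
  inCMB <- SWIcascade:::.sphereMask(g, c(32, 32, 16), 2.5)
  expect_lt(mean(imgValues(swi)[inCMB]), mean(pair@magnitude[inCMB]))

  bad <- new("PhaseMask", weights = array(1, c(2, 2, 2)), m = 1)
  expect_error(composeSWI(pair, bad), "agree")
})

test_that("minimum-intensity projection takes slab-wise voxel minima", {
  set.seed(2)
  v <- array(runif(8 * 8 * 6), c(8, 8, 6))
  swi <- new("SWIVolume", values = v, spacing = c(1, 1, 1),
             filterWindow = 64, m = 4)

  expect_equal(minIntensityProjection(swi, 1), v)
  two <- minIntensityProjection(swi, 2)
  expect_equal(two[, , 1], pmin(v[, , 1], v[, , 2]))
  whole <- minIntensityProjection(swi, 6)
  for (z in 1:6) expect_true(all(whole[, , 1] <= v[, , z]))
  # idempotent at full depth
  again <- minIntensityProjection(new("SWIVolume", values = whole,
                                      spacing = c(1, 1, 1), filterWindow = 64,
                                      m = 4), 1)
  expect_equal(again, whole)
  expect_warning(minIntensityProjection(swi, 10), "clamped")
})

test_that("veins darken more on SWI than on the magnitude image", {
  spec <- phantomSpec(vein_specs = list(list(
    polyline = cbind(40, 24, seq(5, 27, length.out = 10)), radius = 1,
    contrast = 1)), seed = 12)
  s <- makePhantom(spec)
  pair <- magnitudePhase(s)
  sw <- swiPipeline(pair, mip_slab = NULL)
  g <- SWIcascade:::.mmGrids(dim(pair@magnitude), s@spacing)
  d <- SWIcascade:::.polylineDist(g, cbind(40, 24,
                                           seq(5, 27, length.out = 10)))
  inVein <- d <= 1
  near <- d > 2 & d <= 5
  darkerFrac <- function(vol) {
    mean(vol[inVein]) / mean(vol[near])
  }
  # vein-to-surround contrast is deeper after phase-mask weighting
  expect_lt(darkerFrac(imgValues(sw$swi)), darkerFrac(pair@magnitude))
})
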