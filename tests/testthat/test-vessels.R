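test_that("vessel spec validation enforces the geometric invariants", {
  expect_error(vesselGeometrySpec(left_diameter = 0.4), "0.5")
  expect_error(vesselGeometrySpec(basilar_curvature_type = "C",
                                  basilar_amplitude = 0), "normal")
  expect_error(vesselGeometrySpec(basilar_curvature_type = "normal",
                                  basilar_amplitude = 2), "normal")
})

test_that("generated basilar deviation profiles realize the requested type", {
  # straight when normal
  tr <- makeVesselTree(vesselGeometrySpec(basilar_curvature_type = "normal"))
  bm <- basilarMetrics(tr$basilar)
  expect_lt(bm$bl_mm, 1e-6)
  expect_identical(bm$curvature_type, "normal")

  # S type: lateral deviation changes sign exactly once, both lobes at 3 mm
  spec <- vesselGeometrySpec(basilar_curvature_type = "S",
                             basilar_amplitude = 3)
  tr <- makeVesselTree(spec, n_points = 401)
  dev <- tr$basilar[, 1] - spec$confluence_point[1]
  sgn <- sign(dev[abs(dev) > 1e-9])
  expect_identical(sum(diff(sgn) != 0), 1L)
  expect_equal(max(dev), 3, tolerance = 1e-4)
  expect_equal(min(dev), -3, tolerance = 1e-4)

  # width field carries the specified asymmetry at matched arc lengths
  spec2 <- vesselGeometrySpec(left_diameter = 3.5, right_diameter = 2.5)
  tr2 <- makeVesselTree(spec2)
  s <- c(0, 3, 6)
  expect_equal(tr2$widthField(s, "left") - tr2$widthField(s, "right"),
               rep(1, 3))
})

test_that("three-point diameter measurement averages widths at 0/3/6 mm", {
  line <- cbind(seq(0, 10, by = 0.5), 0, 0)
  expect_equal(measureDiameter(line, function(s) rep(3, length(s)))$diameter_mm,
               3)
  wf <- function(s) c(2.8, 3.0, 3.2)[match(s, c(0, 3, 6))]
  expect_equal(measureDiameter(line, wf)$diameter_mm, 3)
  short <- cbind(seq(0, 4, by = 0.5), 0, 0)
  expect_error(measureDiameter(short, function(s) rep(3, length(s))),
               "0.6 cm")
})

test_that("dominance decision and grading follow the diameter-difference bands", {
  r <- assessDominance(3.5, 2.5)
  expect_identical(r$dominant_side, "left")
  expect_equal(r$diff_mm, 1)
  expect_identical(r$grade, "II")

  r0 <- assessDominance(3.0, 3.0)
  expect_identical(r0$dominant_side, "none")
  expect_identical(r0$grade, "ungraded")

  expect_identical(assessDominance(3.0, 2.5)$grade, "I")
  expect_identical(assessDominance(2.5, 3.0)$dominant_side, "right")
  # decoupling: graded but not dominant below 0.3 mm
  rg <- assessDominance(3.0, 2.9)
  expect_identical(rg$dominant_side, "none")
  expect_identical(rg$grade, "I")
})

test_that("grading bands partition [0.04, 2.67] without gap or overlap", {
  diffs <- seq(0.04, 2.67, by = 0.001)
  grades <- vapply(diffs, function(d) assessDominance(3 + d, 3)$grade, "")
  expect_false(any(grades == "ungraded"))
  # each band is one contiguous run: I, II, III in order
  expect_identical(rle(grades)$values, c("I", "II", "III"))
  # printed band edges fall inside their own grade
  expect_identical(assessDominance(3.70, 3)$grade, "I")
  expect_identical(assessDominance(3.71, 3)$grade, "II")
  expect_identical(assessDominance(4.17, 3)$grade, "II")
  expect_identical(assessDominance(4.18, 3)$grade, "III")
  expect_identical(assessDominance(5.67, 3)$grade, "III")
  expect_identical(assessDominance(5.68, 3)$grade, "ungraded")
  expect_identical(assessDominance(3.03, 3)$grade, "ungraded")
})

test_that("bending length matches the sagitta of a circular arc", {
  R <- 40
  for (half in c(0.2, 0.4, 0.6)) {
    th <- seq(-half, half, length.out = 101)
    arc <- cbind(R * sin(th), 0, R * (1 - cos(th)) )
    # rotate so the lateral bulge is along +x, chord along z: swap axes
    arc <- cbind(R * (1 - cos(th)), 0, R * sin(th))
    bm <- basilarMetrics(arc, threshold_mm = 1e9)
    c0 <- bm$bal_mm
    expect_equal(bm$bl_mm, R - sqrt(R^2 - c0^2 / 4), tolerance = 1e-6)
  }
})

test_that("bending length is invariant to rigid motion", {
  spec <- vesselGeometrySpec(basilar_curvature_type = "C",
                             basilar_amplitude = 3)
  tr <- makeVesselTree(spec)
  bm0 <- basilarMetrics(tr$basilar)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- tr$basilar %*% Rz + matrix(c(5, -3, 11), nrow(tr$basilar), 3,
                                      byrow = TRUE)
  bm1 <- basilarMetrics(moved)
  expect_equal(bm1$bl_mm, bm0$bl_mm, tolerance = 1e-9)
  expect_equal(bm1$bal_mm, bm0$bal_mm, tolerance = 1e-9)
})

test_that("curvature classification recovers the generator truth 100/100", {
  set.seed(31)
  types <- sample(c("normal", "C", "reverse_C", "S"), 100, replace = TRUE)
  hits <- 0L
  for (i in seq_along(types)) {
    amp <- if (types[i] == "normal") 0 else runif(1, 4, 8)  # >= 2x threshold
    tr <- makeVesselTree(vesselGeometrySpec(
      basilar_curvature_type = types[i], basilar_amplitude = amp,
      seed = i))
    got <- basilarMetrics(tr$basilar, threshold_mm = 2)$curvature_type
    hits <- hits + as.integer(got == types[i])
  }
  expect_identical(hits, 100L)
})

test_that("morphometry of a generated tree recovers the specified diameters", {
  spec <- vesselGeometrySpec(left_diameter = 3.5, right_diameter = 2.8,
                             basilar_curvature_type = "C",
                             basilar_amplitude = 4)
  row <- vesselMorphometry(makeVesselTree(spec))
  expect_lt(abs(row$left_mm - 3.5), 0.2)
  expect_lt(abs(row$right_mm - 2.8), 0.2)
  expect_identical(row$dominant_side, "left")
  expect_identical(row$grade, "I")
  expect_identical(row$curvature_type, "C")
})

test_that("centerlines round-trip through CSV", {
  tr <- makeVesselTree(vesselGeometrySpec())
  path <- file.path(withr::local_tempdir(), "c.csv")
  writeCenterline(tr$basilar, path)
  expect_equal(readCenterline(path), unname(tr$basilar),
               ignore_attr = TRUE)
})
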