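test_that("phantom truth table mirrors the spec exactly", {
  empty <- makePhantom(phantomSpec(seed = 1))
  expect_identical(nrow(truthLesions(empty)), 0L)
  # background-only phase stays slowly varying and small inside the head
  v <- empty@complexImage@values
  ph <- Arg(v)[Mod(v) > 0.3]   # head interior; exterior is noise-dominated
  expect_lt(stats::quantile(abs(ph), 0.99), 0.5)

  one <- makePhantom(phantomSpec(
    cmb_specs = list(list(center = c(32, 32, 16), diameter = 4,
                          contrast = 1)), seed = 2))
  tl <- truthLesions(one)
  expect_identical(nrow(tl), 1L)
  expect_identical(tl$class, "cmb")
  expect_identical(tl$diameter_mm, 4)
})

test_that("lesion specs outside their size bands or overlapping are rejected", {
  expect_error(phantomSpec(cmb_specs = list(list(center = c(32, 32, 16),
                                                 diameter = 20,
                                                 contrast = 1))),
               "1.5-6.5")
  expect_error(phantomSpec(lacune_specs = list(list(center = c(32, 32, 16),
                                                    diameter = 16))),
               "15")
  expect_error(phantomSpec(cmb_specs = list(list(center = c(200, 32, 16),
                                                 diameter = 4,
                                                 contrast = 1))),
               "field of view")
  expect_error(phantomSpec(
    cmb_specs = list(list(center = c(32, 32, 16), diameter = 4, contrast = 1),
                     list(center = c(33, 32, 16), diameter = 4,
                          contrast = 1))),
    "overlapping")
})

test_that("identical spec and seed give a bit-identical phantom", {
  spec <- randomPhantomSpec(seed = 5)
  a <- makePhantom(spec)
  b <- makePhantom(spec)
  expect_identical(a@complexImage@values, b@complexImage@values)
  expect_identical(a@t1Like, b@t1Like)
  expect_identical(truthLesions(a), truthLesions(b))
})

test_that("implanted objects are conserved in the truth table with negative phase", {
  spec <- randomPhantomSpec(n_cmb = 3, n_vein = 1, n_lacune = 2, seed = 8)
  s <- makePhantom(spec)
  tl <- truthLesions(s)
  expect_identical(sum(tl$class == "cmb"), 3L)
  expect_identical(sum(tl$class == "vein"), 1L)
  expect_identical(sum(tl$class == "lacune"), 2L)

  # phase realism: microbleed interiors are strictly below background phase
  v <- s@complexImage@values
  g <- SWIcascade:::.mmGrids(dim(v), s@spacing)
  cmbs <- tl[tl$class == "cmb", ]
  inMask <- array(FALSE, dim(v))
  for (i in seq_len(nrow(cmbs)))
    inMask <- inMask | SWIcascade:::.sphereMask(
      g, c(cmbs$x_mm[i], cmbs$y_mm[i], cmbs$z_mm[i]), cmbs$diameter_mm[i] / 2)
  expect_lt(mean(Arg(v)[inMask]), mean(Arg(v)[!inMask]))
})

test_that("subject volumes and truth serialize to NIfTI + CSV", {
  s <- makePhantom(randomPhantomSpec(seed = 3), subjectId = "T01")
  dir <- withr::local_tempdir()
  paths <- writeSubject(s, dir)
  expect_true(all(file.exists(paths)))
  mag <- as.array(RNifti::readNifti(paths[3]))
  expect_equal(dim(mag), dim(s@t1Like))
  truth <- utils::read.csv(paths[5])
  expect_identical(nrow(truth), nrow(truthLesions(s)))
})

test_that("cohort generation is reproducible and honors its distributions", {
  spec <- cohortSpec(n_per_group = 30, seed = 7)
  a <- makeCohort(spec)
  b <- makeCohort(spec)
  expect_identical(a$table, b$table)
  expect_identical(names(a$table),
                   c("subject_id", "group", "lacune_count", "cmb_count",
                     "cmb_positive", "dominant_side", "diameter_diff_mm",
                     "curvature_type"))

  # degenerate probabilities pin positivity per group
  deg <- makeCohort(cohortSpec(n_per_group = 10,
                               cmb_positive_prob = c(1, 0), seed = 1))$table
  expect_true(all(deg$cmb_positive[deg$group == "case"]))
  expect_false(any(deg$cmb_positive[deg$group == "control"]))
  expect_true(all(deg$cmb_count[deg$group == "case"] >= 1))

  # law of large numbers on the lacune means at n = 500
  big <- makeCohort(cohortSpec(n_per_group = 500, seed = 11))$table
  for (gi in 1:2) {
    g <- c("case", "control")[gi]
    mu <- c(2.400, 0.672)[gi]
    x <- big$lacune_count[big$group == g]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - mu), 3 * se + 1e-9)
  }
  # dominance flag consistent with the 0.3 mm rule used downstream
  expect_true(all((big$dominant_side != "none") == (big$diameter_diff_mm >= 0.3)))
})
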