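test_that("the same spec generates bit-identical cases", {
  s <- PhantomSpec(gridShape = 48L, tumorVolume = 8, seed = 99L)
  a <- generatePhantom(s)
  b <- generatePhantom(s)
  expect_identical(imageData(ctVolume(a)), imageData(ctVolume(b)))
  expect_identical(imageData(t1Volume(a)), imageData(t1Volume(b)))
  expect_identical(imageData(t2fsVolume(a)), imageData(t2fsVolume(b)))
  expect_identical(imageData(truthLabels(a)), imageData(truthLabels(b)))
})

test_that("the realized lesion volume tracks the requested volume", {
  for (vol in c(5, 30, 120)) {
    case <- generatePhantom(PhantomSpec(tumorVolume = vol, seed = 7L))
    tr <- truthLabels(case)
    realized <- sum(imageData(tr) == vocabulary(tr)["tumor"]) *
      voxelVolume(tr) / 1000
    expect_lt(abs(realized - vol) / vol, 0.10)
  }
  # an impossible lesion is rejected
  expect_error(generatePhantom(PhantomSpec(tumorVolume = 2000, seed = 1L)),
               "fit")
})

test_that("per-modality tissue brightness orderings match the imaging physics", {
  case <- smallPhantom(seed = 13L)
  truth <- truthLabels(case)
  ct <- tissueMeans(ctVolume(case), truth)
  t1 <- tissueMeans(t1Volume(case), truth)
  t2 <- tissueMeans(t2fsVolume(case), truth)
  # CT: bone brightest tissue, dense ordering
  expect_gt(ct["bone"], ct["muscle"])
  expect_gt(ct["muscle"], ct["fat"])
  expect_gt(min(ct), -1001)  # air floor
  # T1w: fat brightest, bone dark; soft-tissue order reversed vs CT
  expect_gt(t1["fat"], max(t1[c("muscle", "liver", "bone", "kidney_left")]))
  soft <- setdiff(nonAirClasses(), "fat")
  expect_lt(stats::cor(ct[soft], t1[soft], method = "spearman"), 0)
  # T2wfs: water-rich organs brighter than suppressed fat and bone
  expect_gt(min(t2[c("kidney_left", "kidney_right", "spleen",
                     "gallbladder", "tumor")]),
            max(t2[c("fat", "bone")]))
  # tumor distinct from kidney parenchyma in CT and T2wfs
  expect_gt(abs(ct["tumor"] - ct["kidney_left"]), 50)
  expect_gt(abs(t2["tumor"] - t2["kidney_left"]), 50)
})

test_that("every declared class is present with nonzero volume", {
  case <- smallPhantom(seed = 3L)
  tr <- truthLabels(case)
  counts <- table(factor(as.vector(imageData(tr)),
                         levels = c(0L, unname(vocabulary(tr)))))
  expect_true(all(counts > 0))
})

test_that("air in the background-zeroed inverted T1w is essentially all zero", {
  case <- smallPhantom(seed = 21L)
  inv <- preprocessVolume(t1Volume(case), "inverted_black")
  airMask <- imageData(truthLabels(case)) == 0L
  expect_gte(mean(imageData(inv)[airMask] == 0), 0.99)
})

test_that("inversion aligns the T1w tissue ordering with CT's", {
  for (seed in c(2L, 31L)) {
    case <- smallPhantom(seed = seed)
    truth <- truthLabels(case)
    cls <- nonAirClasses()
    ct <- tissueMeans(ctVolume(case), truth, cls)
    raw <- tissueMeans(t1Volume(case), truth, cls)
    inv <- tissueMeans(preprocessVolume(t1Volume(case), "inverted_black"),
                       truth, cls)
    expect_gt(stats::cor(inv, ct, method = "spearman"), 0.8)
    expect_lt(stats::cor(raw, ct, method = "spearman"), 0)
  }
})

test_that("cohorts are reproducible with controlled volumes and sides", {
  a <- generateCohort(5, masterSeed = 31L, gridShape = 64L,
                      tumorVolumeRange = c(1, 30))
  b <- generateCohort(5, masterSeed = 31L, gridShape = 64L,
                      tumorVolumeRange = c(1, 30))
  expect_identical(lapply(a, function(cs) imageData(truthLabels(cs))),
                   lapply(b, function(cs) imageData(truthLabels(cs))))
  vols <- vapply(a, function(cs) {
    tr <- truthLabels(cs)
    sum(imageData(tr) == vocabulary(tr)["tumor"]) * voxelVolume(tr) / 1000
  }, numeric(1))
  expect_true(all(vols >= 0.9 & vols <= 33))
  sides <- vapply(a, function(cs) phantomSpec(cs)@tumorSide, character(1))
  expect_true(all(sides %in% c("left", "right")))
  expect_error(generateCohort(3, tumorVolumeRange = c(5, 2)), "lo < hi")
})

test_that("cohort side assignment follows the requested fractions", {
  # sides are drawn before any phantom is built, so probing them via the
  # cohort's own RNG stream is cheap at tiny grid sizes
  cohort <- generateCohort(40, masterSeed = 8L, gridShape = 32L,
                           tumorVolumeRange = c(1, 4),
                           sideFractions = c(left = 0.45, right = 0.55))
  nLeft <- sum(vapply(cohort, function(cs) phantomSpec(cs)@tumorSide,
                      character(1)) == "left")
  # binomial(40, 0.45) 99% interval
  expect_gte(nLeft, stats::qbinom(0.005, 40, 0.45))
  expect_lte(nLeft, stats::qbinom(0.995, 40, 0.45))
})

test_that("a written cohort reads back unchanged", {
  dir <- file.path(tempdir(), "cohort_io")
  unlink(dir, recursive = TRUE)
  cases <- generateCohort(2, masterSeed = 17L, gridShape = 48L,
                          tumorVolumeRange = c(2, 10))
  writeCohort(cases, dir)
  t1 <- readVolume(file.path(dir, "case_01", "t1.nii.gz"), modality = "T1w")
  expect_equal(imageData(t1), imageData(t1Volume(cases[[1]])))
  tr <- readLabelMap(file.path(dir, "case_01", "truth.nii.gz"))
  expect_identical(imageData(tr), imageData(truthLabels(cases[[1]])))
  expect_identical(vocabulary(tr), vocabulary(truthLabels(cases[[1]])))
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
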