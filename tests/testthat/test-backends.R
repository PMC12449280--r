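rawWindow <- function(class_name, lo, hi, min_mm3 = 0,
                      side = "none", priority = 1L) {
  data.frame(class_name = class_name, lo = lo, hi = hi,
             min_component_mm3 = min_mm3, side_constraint = side,
             priority = priority, stringsAsFactors = FALSE)
}

test_that("window segmentation labels exactly the in-window component", {
  x <- array(-1000, c(12, 12, 12))      # air everywhere
  cube <- array(FALSE, c(12, 12, 12)); cube[2:11, 2:11, 2:11] <- TRUE
  x[cube] <- 40                          # one 10^3 soft-tissue cube
  v <- Volume(x)
  out <- windowSegment(v, rawWindow("soft", 20, 60), scale = "raw")
  expect_identical(imageData(out) == 1L, cube)
  # all-air volume yields an empty map
  air <- Volume(array(-1000, c(8, 8, 8)))
  empty <- windowSegment(air, rawWindow("soft", 20, 60), scale = "raw")
  expect_true(all(imageData(empty) == 0L))
  expect_error(windowSegment(v, data.frame()), "non-empty")
})

test_that("window segmentation is deterministic and the size filter is monotone", {
  set.seed(21)
  v <- Volume(array(stats::rnorm(20^3, 0, 50), c(20, 20, 20)))
  w <- rawWindow("blob", 30, 200, min_mm3 = 5)
  a <- windowSegment(v, w, scale = "raw")
  b <- windowSegment(v, w, scale = "raw")
  expect_identical(imageData(a), imageData(b))
  # lowering the size threshold never removes labelled voxels
  w0 <- rawWindow("blob", 30, 200, min_mm3 = 0)
  none <- windowSegment(v, w0, scale = "raw")
  expect_true(all(imageData(none)[imageData(a) == 1L] == 1L))
  expect_gte(sum(imageData(none) == 1L), sum(imageData(a) == 1L))
})

test_that("side constraints never cross the midline and priority resolves overlap", {
  x <- array(0, c(10, 6, 6))
  x[2, 3, 3] <- 50; x[9, 3, 3] <- 50
  v <- Volume(x)
  w <- rbind(rawWindow("left_thing", 20, 60, side = "left_of_midline",
                       priority = 2L),
             rawWindow("right_thing", 20, 60, side = "right_of_midline",
                       priority = 1L))
  out <- imageData(windowSegment(v, w, scale = "raw"))
  expect_identical(out[2, 3, 3], 1L)
  expect_identical(out[9, 3, 3], 2L)
  xi <- slice.index(out, 1)
  expect_true(all(out[xi > 5.5] != 1L))
  expect_true(all(out[xi < 5.5] != 2L))
  # overlapping windows: higher priority claims the voxel
  w2 <- rbind(rawWindow("lowprio", 20, 60, priority = 1L),
              rawWindow("highprio", 20, 60, priority = 9L))
  out2 <- imageData(windowSegment(v, w2, scale = "raw"))
  expect_true(all(out2[out2 != 0L] == 2L))
})

test_that("relative scale maps window bounds onto the volume's range", {
  x <- array(0, c(8, 8, 8)); x[4:5, 4:5, 4:5] <- 1000
  v <- Volume(x)
  w <- rawWindow("bright", 0.9, 1.0)
  out <- windowSegment(v, w, scale = "relative")
  expect_identical(imageData(out) == 1L, x == 1000)
})

test_that("the external adapter round-trips through a stub command", {
  lm <- LabelMap(array(sample(0:2, 6^3, replace = TRUE), c(6, 6, 6)),
                 spacing = 2, vocabulary = c(organ = 1L, lesion = 2L))
  fixture <- file.path(tempdir(), "stub_labels.nii.gz")
  writeVolume(lm, fixture)
  sidecar <- sub("nii.gz$", "labels.json", fixture)
  v <- Volume(array(0, c(6, 6, 6)), spacing = 2)
  out <- externalSegment(paste("cp", fixture, "{output}.nii.gz && cp",
                               sidecar, "{output}.labels.json # {input}"),
                         v)
  expect_identical(imageData(out), imageData(lm))
  expect_identical(vocabulary(out), vocabulary(lm))
})

test_that("the external adapter surfaces failures and bad templates", {
  v <- Volume(array(0, c(4, 4, 4)))
  expect_error(externalSegment("doesnothing --in {input}", v), "placeholder")
  expect_error(externalSegment("false # {input} {output}", v),
               "exit status")
  expect_error(externalSegment("true # {input} {output}", v),
               "no output")
})

test_that("multi-file external outputs merge via the class mapping", {
  dir <- file.path(tempdir(), "multi_out")
  unlink(dir, recursive = TRUE)
  dir.create(dir)
  a <- array(0L, c(5, 5, 5)); a[1:2, , ] <- 1L
  b <- array(0L, c(5, 5, 5)); b[4:5, , ] <- 1L
  writeVolume(LabelMap(a, vocabulary = c(mask = 1L)),
              file.path(dir, "kidney.nii.gz"), sidecar = FALSE)
  writeVolume(LabelMap(b, vocabulary = c(mask = 1L)),
              file.path(dir, "tumor.nii.gz"), sidecar = FALSE)
  v <- Volume(array(0, c(5, 5, 5)))
  out <- externalSegment(sprintf("mkdir -p {output} && cp %s/*.nii.gz {output}/ # {input}", dir),
                         v, classMapping = c(kidney = 3L, tumor = 7L))
  expect_identical(sort(unique(as.vector(imageData(out)))), c(0L, 3L, 7L))
  expect_true(all(imageData(out)[a == 1L] == 3L))
  expect_true(all(imageData(out)[b == 1L] == 7L))
})

test_that("the default window table is well formed", {
  w <- defaultWindows()
  expect_identical(attr(w, "scale"), "relative")
  expect_true(all(w$lo < w$hi))
  expect_setequal(
    w$class_name,
    setdiff(defaultTissueTable()$class, "air"))
})
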