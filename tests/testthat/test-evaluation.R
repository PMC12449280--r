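test_that("dice handles the boundary cases and a hand-counted overlap", {
  a <- array(FALSE, c(4, 4, 1)); a[1:2, 1:2, 1] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, c(4, 4, 1)); b[3:4, 3:4, 1] <- TRUE
  expect_equal(dice(a, b), 0)
  # two 2x2 squares overlapping in 2 voxels: 2*2/(4+4)
  c2 <- array(FALSE, c(4, 4, 1)); c2[2:3, 1:2, 1] <- TRUE
  expect_equal(dice(a, c2), 0.5)
  empty <- array(FALSE, c(4, 4, 1))
  expect_true(is.na(dice(empty, empty)))
  expect_error(dice(a, array(FALSE, c(3, 3, 1))), "shapes")
})

test_that("dice equals brute-force counting and is symmetric on random masks", {
  set.seed(100)
  for (i in 1:200) {
    a <- array(stats::runif(8^3) < 0.3, c(8, 8, 8))
    b <- array(stats::runif(8^3) < 0.3, c(8, 8, 8))
    d <- dice(a, b)
    expect_identical(d, bruteDice(a, b))
    expect_identical(d, dice(b, a))
  }
})

test_that("case evaluation reproduces per-class dice and volumes", {
  case <- smallPhantom(seed = 4L)
  truth <- truthLabels(case)
  pred <- windowSegment(ctVolume(case), defaultWindows())
  recs <- evaluateCase(pred, truth, case_id = "c1", sequence = "CT",
                       variant = "unprocessed")
  expect_setequal(recs$class_name, names(vocabulary(truth)))
  voc <- vocabulary(truth)
  for (cl in sample(recs$class_name, 5)) {
    manual <- dice(imageData(pred) == vocabulary(pred)[cl],
                   imageData(truth) == voc[cl])
    expect_equal(recs$dsc[recs$class_name == cl], manual)
  }
  expect_equal(recs$ref_volume_cm3,
               vapply(recs$class_name, function(cl)
                 sum(imageData(truth) == voc[cl]) * voxelVolume(truth) / 1000,
                 numeric(1)), ignore_attr = TRUE)
  # identity prediction scores 1 everywhere
  perfect <- evaluateCase(truth, truth)
  expect_true(all(perfect$dsc == 1))
  # empty prediction scores 0 where the reference class exists
  none <- LabelMap(array(0L, dim(truth)), spacing = spacing(truth),
                   vocabulary = vocabulary(truth))
  zeros <- evaluateCase(none, truth)
  expect_true(all(zeros$dsc[zeros$ref_volume_cm3 > 0] == 0))
})

test_that("merging prediction classes through the mapping unions their masks", {
  dat <- array(0L, c(6, 6, 1))
  dat[1:2, 1:3, 1] <- 1L; dat[4:5, 1:3, 1] <- 2L
  pred <- LabelMap(dat, vocabulary = c(part_a = 1L, part_b = 2L))
  refdat <- array(0L, c(6, 6, 1)); refdat[1:5, 1:3, 1] <- 3L
  ref <- LabelMap(refdat, vocabulary = c(whole = 3L))
  mapping <- c(part_a = "whole", part_b = "whole")
  rec <- evaluateCase(pred, ref, mapping = mapping)
  dA <- dice(dat == 1L, refdat == 3L)
  dB <- dice(dat == 2L, refdat == 3L)
  dU <- dice(dat > 0L, refdat == 3L)
  expect_equal(rec$dsc, dU)
  # disjoint parts: the union can only do at least as well as each part
  expect_gte(dU, max(dA, dB))
})

test_that("summaries report means, seeded bootstrap CIs and undefined counts", {
  tab <- data.frame(
    case_id = rep(c("a", "b", "c"), each = 2),
    sequence = "T1w", variant = "inverted_black",
    class_name = rep(c("k", "t"), 3),
    dsc = c(0.5, 0.7, 0.5, 0.7, 0.5, NA),
    ref_volume_cm3 = 1, pred_volume_cm3 = 1)
  s <- summarizeDice(tab, B = 200, seed = 3)
  expect_equal(s$mean_dsc, mean(c(0.5, 0.7, 0.5, 0.7, 0.5)))
  expect_equal(s$n_undefined, 1L)
  s2 <- summarizeDice(tab, B = 200, seed = 3)
  expect_identical(s, s2)                      # seeded determinism
  single <- summarizeDice(tab[1, ], B = 50)
  expect_equal(single$ci_lo, single$mean_dsc)  # one record: degenerate CI
  expect_equal(single$ci_hi, single$mean_dsc)
  same <- tab; same$dsc <- 0.4
  sc <- summarizeDice(same, B = 50)
  expect_equal(sc$ci_lo, sc$ci_hi)             # identical values: width 0
})

test_that("localization categories partition all outcomes", {
  ref <- array(FALSE, c(6, 6, 6)); ref[2:3, 2:3, 2:3] <- TRUE
  expect_identical(classifyLocalization(array(FALSE, dim(ref)), ref),
                   "not_detected")
  expect_identical(classifyLocalization(ref, ref), "correct")
  far <- array(FALSE, c(6, 6, 6)); far[5:6, 5:6, 5:6] <- TRUE
  expect_identical(classifyLocalization(far, ref), "incorrect")
  expect_error(classifyLocalization(ref, array(FALSE, dim(ref))), "empty")
  set.seed(12)
  for (i in 1:50) {
    p <- array(stats::runif(6^3) < 0.1, c(6, 6, 6))
    got <- classifyLocalization(p, ref)
    expect_true(got %in% c("correct", "incorrect", "not_detected"))
  }
  # a minimum-overlap fraction makes grazing overlap insufficient
  graze <- array(FALSE, c(6, 6, 6)); graze[3, 3, 3] <- TRUE
  expect_identical(classifyLocalization(graze, ref, minOverlap = 0.5),
                   "incorrect")
})

test_that("volume stratification splits at the median", {
  two <- data.frame(case_id = c("a", "b"), sequence = "T1w",
                    variant = "x", class_name = "tumor",
                    dsc = c(0.2, 0.8), ref_volume_cm3 = c(10, 30),
                    pred_volume_cm3 = 0)
  st <- stratifyByVolume(two)
  expect_equal(st$median_volume_cm3, 20)
  expect_equal(st$mean_dsc_below, 0.2)
  expect_equal(st$mean_dsc_above, 0.8)
  # all-equal volumes: empty lower stratum is flagged
  eq <- two; eq$ref_volume_cm3 <- 5
  expect_false(is.na(stratifyByVolume(eq)$flag))
  expect_error(stratifyByVolume(two[1, ]), "at least 2")
  # agrees with an independent group-by on a larger seeded table
  set.seed(77)
  n <- 50
  tab <- data.frame(case_id = sprintf("c%02d", 1:n), sequence = "T1w",
                    variant = "inverted_black", class_name = "tumor",
                    dsc = stats::runif(n), ref_volume_cm3 = exp(stats::runif(n, 0, 5)),
                    pred_volume_cm3 = 0)
  st2 <- stratifyByVolume(tab)
  med <- stats::median(tab$ref_volume_cm3)
  expect_equal(st2$mean_dsc_below, mean(tab$dsc[tab$ref_volume_cm3 < med]))
  expect_equal(st2$mean_dsc_above, mean(tab$dsc[tab$ref_volume_cm3 >= med]))
})
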