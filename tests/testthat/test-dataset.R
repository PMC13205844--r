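test_that("subject split has the requested sizes and is seed-deterministic", {
  ids <- sprintf("S%03d", 1:98)
  sp <- subjectSplit(ids, c(68, 15, 15), seed = 42)
  sets <- splitSets(sp)
  expect_length(sets$train, 68)
  expect_length(sets$val, 15)
  expect_length(sets$test, 15)
  expect_setequal(unlist(sets), ids)
  sp2 <- subjectSplit(ids, c(68, 15, 15), seed = 42)
  expect_identical(splitSets(sp2), sets)
  expect_false(identical(splitSets(subjectSplit(ids, c(68, 15, 15), 43)),
                         sets))
  expect_error(subjectSplit(ids, c(69, 15, 15)), "sum")
})

test_that("split is uniform: each subject lands in test with frequency 15/98", {
  ids <- sprintf("S%03d", 1:98)
  counts <- setNames(numeric(98), ids)
  n_seeds <- 600
  for (s in seq_len(n_seeds)) {
    sp <- subjectSplit(ids, c(68, 15, 15), seed = s)
    counts[splitSets(sp)$test] <- counts[splitSets(sp)$test] + 1
  }
  freq <- counts / n_seeds
  # binomial SE at p = 15/98 over 600 seeds is ~0.0147
  expect_true(all(abs(freq - 15 / 98) < 5 * 0.0147))
  expect_equal(mean(freq), 15 / 98, tolerance = 1e-9)
})

test_that("leakage checker passes clean splits and names offenders", {
  co <- small_cohort(6)
  ids <- unique(vapply(co, subjectId, ""))
  sp <- subjectSplit(ids, c(4, 1, 1), seed = 1)
  expect_true(assertNoLeakage(sp, co)$pass)
  bad <- sp
  bad@trainIds <- c(bad@trainIds, bad@testIds[1])
  res <- assertNoLeakage(bad, co)
  expect_false(res$pass)
  expect_match(res$problems, bad@testIds[1], all = FALSE)
  # unassigned subject
  sp2 <- subjectSplit(ids[-1], c(3, 1, 1), seed = 1)
  res2 <- assertNoLeakage(sp2, co)
  expect_false(res2$pass)
  expect_match(res2$problems, ids[1], all = FALSE)
})

test_that("an image-level random split almost surely leaks subjects", {
  co <- small_cohort(10)
  subj <- vapply(co, subjectId, "")
  fails <- 0
  for (s in 1:100) {
    # naive image-level split: assign images 14/3/3, then read off the
    # subject membership of each set
    idx <- withr::with_seed(s, sample(length(co)))
    sets <- list(unique(subj[idx[1:14]]), unique(subj[idx[15:17]]),
                 unique(subj[idx[18:20]]))
    leaked <- tryCatch({
      sp <- new("CohortSplit", trainIds = sets[[1]], valIds = sets[[2]],
                testIds = sets[[3]], seed = s)
      !assertNoLeakage(sp, co)$pass
    }, error = function(e) TRUE)  # validity itself rejects duplicated subjects
    if (leaked) fails <- fails + 1
  }
  expect_gt(fails / 100, 0.95)
})

test_that("brightness jitter scales, clips, and leaves landmarks alone", {
  img <- small_cohort(2)[[1]]
  same <- brightnessJitter(img, 1.0)
  expect_identical(same@pixels, img@pixels)
  up <- brightnessJitter(img, 1.3)
  px <- pixelArray(img)
  expect_identical(pixelArray(up),
                   array(as.integer(pmin(round(px * 1.3), 255)), dim(px)))
  # explicit clip bound
  hot <- tiny_image(grid_landmarks("frontal"))
  hot@pixels[] <- as.raw(200)
  expect_true(all(pixelArray(brightnessJitter(hot, 1.3)) == 255))
  for (f in c(0.7, 0.85, 1.25)) {
    expect_identical(landmarks(brightnessJitter(img, f)), landmarks(img))
  }
  expect_error(brightnessJitter(img, 0))
})

test_that("augmentation appends jittered copies deterministically", {
  co <- small_cohort(4)
  tr <- co[1:4]
  cfg <- augmentationConfig(seed = 11)
  aug <- augmentTrainingSet(tr, cfg)
  expect_length(aug, 8)
  expect_identical(aug[[1]]@pixels, tr[[1]]@pixels)   # originals first
  aug2 <- augmentTrainingSet(tr, cfg)
  expect_identical(lapply(aug, slot, "pixels"), lapply(aug2, slot, "pixels"))
  expect_identical(augmentTrainingSet(tr, augmentationConfig(copies_per_image = 0)),
                   tr)
  expect_length(augmentTrainingSet(tr, augmentationConfig(copies_per_image = 2)),
                12)
  expect_error(augmentationConfig(brightness_low = 1.5, brightness_high = 1.2))
})

test_that("resizeNormalize produces [0,1] inputs and schema-length targets", {
  img <- small_cohort(2)[[1]]
  s <- resizeNormalize(img)
  expect_equal(dim(s$input), c(128, 128, 3))
  expect_true(all(s$input >= 0 & s$input <= 1))
  expect_length(s$target, 44)
  expect_true(all(s$target > 0 & s$target < 1))
  # all-white image maps to an all-one input array
  white <- tiny_image(grid_landmarks("frontal"))
  white@pixels[] <- as.raw(255)
  expect_true(all(resizeNormalize(white)$input == 1))
  # landmark at the centre normalizes to (0.5, 0.5)
  lm <- grid_landmarks("frontal")
  lm$x[1] <- 50; lm$y[1] <- 60
  s2 <- resizeNormalize(tiny_image(lm, width = 100L, height = 120L))
  expect_equal(s2$target[1:2], c(0.5, 0.5), tolerance = 1e-12)
})

test_that("denormalization inverts normalization exactly", {
  img <- small_cohort(2)[[2]]
  s <- resizeNormalize(img)
  back <- denormalizeLandmarks(s$target, s$width, s$height,
                               landmarkSchema(imageView(img)))
  expect_identical(back$name, landmarks(img)$name)
  expect_equal(back$x, landmarks(img)$x, tolerance = 1e-9)
  expect_equal(back$y, landmarks(img)$y, tolerance = 1e-9)
  expect_equal(denormalizeLandmarks(c(0.5, 0.5), 1034, 1150),
               data.frame(x = 517, y = 575))
  expect_true(all(denormalizeLandmarks(rep(0, 10), 50, 50)[, c("x", "y")] == 0))
  expect_error(denormalizeLandmarks(c(0.5, 0.5, 0.5), 100, 100), "even")
})
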