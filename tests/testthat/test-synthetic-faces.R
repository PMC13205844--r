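test_that("subject sampling is deterministic and seed-sensitive", {
  a <- sampleSubject(3, 42)
  b <- sampleSubject(3, 42)
  expect_identical(a@faceWidthPx, b@faceWidthPx)
  expect_identical(a@shapeLatents, b@shapeLatents)
  expect_identical(a@skinTone, b@skinTone)
  c <- sampleSubject(3, 43)
  expect_false(identical(a@shapeLatents, c@shapeLatents))
})

test_that("image dimension draws match the target Normal(1034, 56) x (1150, 57)", {
  widths <- vapply(1:4000, function(i) sampleSubject(i, 7)@faceWidthPx, 0)
  heights <- vapply(1:4000, function(i) sampleSubject(i, 7)@faceHeightPx, 0)
  # Monte-Carlo tolerance: SE(mean) ~ 56/sqrt(4000) ~ 0.9
  expect_lt(abs(mean(widths) - 1034), 3)
  expect_lt(abs(sd(widths) - 56), 3)
  expect_lt(abs(mean(heights) - 1150), 3)
  expect_lt(abs(sd(heights) - 57), 3)
  expect_true(all(abs(widths - 1034) <= 3 * 56))
})

test_that("templates have the schema counts and midline/symmetry structure", {
  p <- sampleSubject(1, 42)
  fr <- landmarkTemplate(p, "frontal")
  pr <- landmarkTemplate(p, "profile")
  expect_equal(nrow(fr), 22)
  expect_equal(nrow(pr), 15)
  expect_identical(fr$name, landmarkNames(landmarkSchema("frontal")))
  expect_identical(pr$name, landmarkNames(landmarkSchema("profile")))
  midline <- c("Tr", "G", "N", "Prn", "Sn", "Phi", "Ls", "Stm", "Li",
               "Pg", "Gn", "Me")
  expect_equal(length(unique(fr$x[fr$name %in% midline])), 1L)
  expect_error(landmarkTemplate(p, "sideways"))
})

test_that("zero asymmetry gives exactly mirror-symmetric paired landmarks", {
  p <- sampleSubject(5, 42)
  p@shapeLatents["asym"] <- 0
  fr <- landmarkTemplate(p, "frontal")
  cx <- unique(fr$x[fr$name == "Prn"])
  for (pairs in list(c("GoL", "GoR"), c("ChL", "ChR"), c("AlL", "AlR"),
                     c("ExL", "ExR"), c("EndL", "EndR"))) {
    xL <- fr$x[fr$name == pairs[1]]
    xR <- fr$x[fr$name == pairs[2]]
    expect_equal(xL - cx, cx - xR, tolerance = 1e-9)
    expect_equal(fr$y[fr$name == pairs[1]], fr$y[fr$name == pairs[2]])
  }
})

test_that("rendering is deterministic and landmarks stay strictly in bounds", {
  p <- sampleSubject(2, 42)
  a <- renderView(p, "frontal")
  b <- renderView(p, "frontal")
  expect_identical(a@pixels, b@pixels)
  expect_identical(landmarks(a), landmarks(b))
  for (img in small_cohort(4)) {
    lm <- landmarks(img)
    expect_true(all(lm$x > 0 & lm$x < imageWidth(img) - 1))
    expect_true(all(lm$y > 0 & lm$y < imageHeight(img) - 1))
    expect_length(validateAnnotation(img), 0)
  }
})

test_that("every landmark sits on local intensity structure", {
  # learnability: the max gradient magnitude within 5 px of each landmark
  # must exceed the image's median gradient magnitude
  imgs <- small_cohort(10)
  for (img in imgs) {
    px <- pixelArray(img)
    lum <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
    gy <- abs(diff(lum))
    gx <- abs(t(diff(t(lum))))
    grad <- gy[, -ncol(gy)] + gx[-nrow(gx), ]
    med <- median(grad)
    lm <- landmarks(img)
    for (i in seq_len(nrow(lm))) {
      r0 <- max(1, round(lm$y[i]) - 4); r1 <- min(nrow(grad), round(lm$y[i]) + 6)
      c0 <- max(1, round(lm$x[i]) - 4); c1 <- min(ncol(grad), round(lm$x[i]) + 6)
      expect_gt(max(grad[r0:r1, c0:c1]), med)
    }
  }
})

test_that("cohort generation yields two images per subject, byte-reproducible", {
  co <- generateCohort(3, 55)
  expect_length(co, 6)
  expect_identical(subjectId(co[[1]]), subjectId(co[[2]]))
  expect_setequal(vapply(co[1:2], imageView, ""), c("frontal", "profile"))
  co2 <- generateCohort(3, 55)
  expect_identical(lapply(co, slot, "pixels"), lapply(co2, slot, "pixels"))
  expect_identical(lapply(co, landmarks), lapply(co2, landmarks))
  expect_error(generateCohort(0))
})

test_that("annotator jitter has the Rayleigh mean displacement and zero-noise limit", {
  truth <- data.frame(name = sprintf("P%04d", 1:5000),
                      x = runif(5000, 100, 900), y = runif(5000, 100, 1000))
  jit <- simulateAnnotator(truth, annotatorModel(1.0, seed = 9), scale = 0.1)
  expect_identical(simulateAnnotator(truth, annotatorModel(1.0, seed = 9), 0.1),
                   jit)
  disp_mm <- sqrt((jit$x - truth$x)^2 + (jit$y - truth$y)^2) * 0.1
  # mean of a Rayleigh with per-axis SD sigma is sigma * sqrt(pi / 2)
  expect_equal(mean(disp_mm), 1.0 * sqrt(pi / 2), tolerance = 0.05)
  near0 <- simulateAnnotator(truth, annotatorModel(1e-9, seed = 2), 0.1)
  expect_equal(near0$x, truth$x, tolerance = 1e-6)
})

test_that("export writes PNGs, LabelMe JSONs, and a manifest", {
  dir <- withr::local_tempdir()
  co <- small_cohort(2)[1:2]
  man <- exportCohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(file.path(dir, man$image))))
  json <- file.path(dir, sub("\\.png$", ".json", man$image[1]))
  expect_true(file.exists(json))
  back <- readLabelmeJSON(json, landmarkSchema(man$view[1]))
  expect_equal(landmarks(back)$x, landmarks(co[[1]])$x, tolerance = 1e-6)
})
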