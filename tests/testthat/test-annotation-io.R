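test_that("LabelMe JSON round-trips names, order, and coordinates", {
  dir <- withr::local_tempdir()
  img <- small_cohort(2)[[1]]
  path <- file.path(dir, "s1.json")
  png::writePNG(pixelArray(img) / 255, file.path(dir, "s1.png"))
  writeLabelmeJSON(img, path, image_path = "s1.png")
  back <- readLabelmeJSON(path, landmarkSchema("frontal"))
  expect_identical(landmarks(back)$name, landmarks(img)$name)
  expect_equal(landmarks(back)$x, landmarks(img)$x, tolerance = 1e-6)
  expect_equal(landmarks(back)$y, landmarks(img)$y, tolerance = 1e-6)
  # writer output is deterministic
  writeLabelmeJSON(img, file.path(dir, "s1b.json"), image_path = "s1.png")
  expect_identical(readLines(path), readLines(file.path(dir, "s1b.json")))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(doc$imageHeight, imageHeight(img))
  expect_equal(doc$imageWidth, imageWidth(img))
  expect_length(doc$shapes, 22)
  expect_identical(doc$shapes[[1]]$shape_type, "point")
})

test_that("reader reorders shuffled labels to schema order", {
  dir <- withr::local_tempdir()
  schema <- landmarkSchema("profile")
  lm <- grid_landmarks("profile")
  img <- tiny_image(lm, "profile")
  png::writePNG(pixelArray(img) / 255, file.path(dir, "p.png"))
  for (k in 1:5) {
    shuffled <- img
    perm <- sample(nrow(lm))
    shuffled@landmarks <- lm[perm, ]
    path <- file.path(dir, sprintf("p%d.json", k))
    writeLabelmeJSON(shuffled, path, image_path = "p.png")
    back <- readLabelmeJSON(path, schema)
    expect_identical(landmarks(back)$name, landmarkNames(schema))
    expect_equal(landmarks(back)$x, lm$x, tolerance = 1e-9)
  }
})

test_that("reader errors on missing or duplicate landmarks, warns on extras", {
  dir <- withr::local_tempdir()
  schema <- landmarkSchema("frontal")
  img <- tiny_image(grid_landmarks("frontal"))
  png::writePNG(pixelArray(img) / 255, file.path(dir, "f.png"))
  # drop one landmark
  crippled <- img
  crippled@landmarks <- img@landmarks[img@landmarks$name != "Prn", ]
  p1 <- file.path(dir, "missing.json")
  writeLabelmeJSON(crippled, p1, image_path = "f.png")
  expect_error(readLabelmeJSON(p1, schema), "Prn")
  # duplicate a landmark by rewriting the json
  doc <- jsonlite::fromJSON(file.path(dir, "missing.json"),
                            simplifyVector = FALSE)
  writeLabelmeJSON(img, file.path(dir, "full.json"), image_path = "f.png")
  doc <- jsonlite::fromJSON(file.path(dir, "full.json"),
                            simplifyVector = FALSE)
  doc$shapes <- c(doc$shapes, doc$shapes[1])
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"),
             file.path(dir, "dup.json"))
  expect_error(readLabelmeJSON(file.path(dir, "dup.json"), schema),
               "duplicate")
  # unknown extra label is ignored with a warning
  doc$shapes[[length(doc$shapes)]]$label <- "NotALandmark"
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"),
             file.path(dir, "extra.json"))
  expect_warning(back <- readLabelmeJSON(file.path(dir, "extra.json"),
                                         schema), "NotALandmark")
  expect_equal(nrow(landmarks(back)), 22)
})

test_that("full anatomical names are accepted as aliases", {
  dir <- withr::local_tempdir()
  schema <- landmarkSchema("profile")
  img <- tiny_image(grid_landmarks("profile"), "profile")
  png::writePNG(pixelArray(img) / 255, file.path(dir, "p.png"))
  writeLabelmeJSON(img, file.path(dir, "p.json"), image_path = "p.png")
  doc <- jsonlite::fromJSON(file.path(dir, "p.json"), simplifyVector = FALSE)
  full <- c(Tr = "Trichion", Prn = "Pronasale", Me = "Menton", Go = "Gonion")
  for (i in seq_along(doc$shapes)) {
    lab <- doc$shapes[[i]]$label
    if (lab %in% names(full)) doc$shapes[[i]]$label <- unname(full[lab])
  }
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"),
             file.path(dir, "alias.json"))
  back <- readLabelmeJSON(file.path(dir, "alias.json"), schema)
  expect_identical(landmarks(back)$name, landmarkNames(schema))
})

test_that("validateAnnotation flags out-of-bounds and non-finite coordinates", {
  img <- tiny_image(grid_landmarks("frontal"))
  expect_length(validateAnnotation(img), 0)
  bad <- img
  bad@landmarks$x[3] <- -3
  v <- validateAnnotation(bad)
  expect_length(v, 1)
  expect_match(v, "out-of-bounds")
  bad2 <- img
  bad2@landmarks$y[5] <- NaN
  expect_match(validateAnnotation(bad2), "non-finite", all = FALSE)
})

test_that("the QC gate drops whole subjects with corrupt annotations", {
  imgs <- list()
  for (i in 1:10) {
    lmf <- grid_landmarks("frontal")
    lmp <- grid_landmarks("profile")
    id <- sprintf("S%03d", i)
    imgs <- c(imgs, list(tiny_image(lmf, "frontal", id),
                         tiny_image(lmp, "profile", id)))
  }
  # corrupt one view of two subjects
  imgs[[3]]@landmarks$x[1] <- -10        # subject S002 frontal
  imgs[[12]]@landmarks$y[2] <- 1e6       # subject S006 profile
  gate <- qcGate(imgs)
  expect_setequal(gate$dropped, c("S002", "S006"))
  expect_length(gate$images, 16)
  survivors <- unique(vapply(gate$images, subjectId, ""))
  expect_length(survivors, 8)
})
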