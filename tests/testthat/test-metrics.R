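test_that("pixel errors convert to mm by Euclidean distance times scale", {
  expect_equal(pxErrorToMm(c(10, 10), c(10, 10)), 0)
  expect_equal(pxErrorToMm(c(100, 100), c(103, 104), 0.1), 0.5)
  # homogeneity: scaling both points by k scales the error by k
  p1 <- c(123.4, 567.8); p2 <- c(130.1, 560.2)
  expect_equal(pxErrorToMm(3 * p1, 3 * p2), 3 * pxErrorToMm(p1, p2))
  # vectorized over rows
  e <- pxErrorToMm(rbind(c(0, 0), c(1, 1)), rbind(c(3, 4), c(1, 1)), 0.1)
  expect_equal(e, c(0.5, 0))
})

test_that("effective scale is linear in original width", {
  expect_equal(effectiveScale(1034), 0.8078125)
  expect_equal(effectiveScale(128), 0.1)
  expect_equal(effectiveScale(2 * 777), 2 * effectiveScale(777))
})

test_that("scale consistency reproduces CV% and matches a two-pass oracle", {
  r <- scaleConsistency(c(0.808, 0.808))
  expect_equal(r$cv_pct, 0)
  widths <- withr::with_seed(5, rnorm(20, 1034, 56))
  scales <- effectiveScale(widths)
  r2 <- scaleConsistency(scales)
  # independent two-pass mean/SD recomputation
  m <- sum(scales) / length(scales)
  s <- sqrt(sum((scales - m)^2) / (length(scales) - 1))
  expect_equal(r2$mean, m, tolerance = 1e-12)
  expect_equal(r2$cv_pct, 100 * s / m, tolerance = 1e-12)
  expect_true(r2$pass)
  expect_error(scaleConsistency(0.8), "two")
})

test_that("significance against zero follows the closed-form t distribution", {
  x <- withr::with_seed(8, rnorm(20, 0.5, 0.3))
  r <- significanceVsZero(x)
  tt <- mean(x) / (sd(x) / sqrt(20))
  expect_equal(r$t, tt, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(tt), 19), tolerance = 1e-12)
  expect_lt(r$p_value, 0.001)
  # degenerate contracts
  d1 <- significanceVsZero(rep(0.4, 5))
  expect_true(d1$degenerate)
  expect_equal(d1$p_value, 0)
  d0 <- significanceVsZero(rep(0, 5))
  expect_equal(d0$p_value, 1)
})

test_that("per-landmark error tables match a flat independent recomputation", {
  co <- small_cohort(4)
  truth <- co[1:4]
  # predictions: truth displaced by a known per-image offset
  preds <- lapply(seq_along(truth), function(i) {
    lm <- landmarks(truth[[i]])
    lm$x <- lm$x + 3 * i
    lm$y <- lm$y + 4 * i
    lm
  })
  ev <- perLandmarkErrors(truth, preds, scale = 0.1)
  expect_equal(sort(unique(ev$table$error_mm)), (1:4) * 0.5, tolerance = 1e-9)
  flat <- unlist(lapply(seq_along(truth), function(i) {
    tl <- landmarks(truth[[i]]); pl <- preds[[i]]
    sqrt((tl$x - pl$x)^2 + (tl$y - pl$y)^2) * 0.1
  }))
  expect_equal(ev$overall$mean_mm, mean(flat), tolerance = 1e-12)
  expect_equal(ev$overall$sd_mm, sd(flat), tolerance = 1e-12)
  # identical predictions give an all-zero table
  ev0 <- perLandmarkErrors(truth, lapply(truth, landmarks))
  expect_true(all(ev0$table$error_mm == 0))
  # single off landmark: only that landmark nonzero
  p1 <- lapply(truth, landmarks)
  p1[[1]]$x[3] <- p1[[1]]$x[3] + 3
  p1[[1]]$y[3] <- p1[[1]]$y[3] + 4
  ev1 <- perLandmarkErrors(truth, p1)
  nm <- landmarks(truth[[1]])$name[3]
  expect_equal(sum(ev1$table$error_mm > 0), 1)
  n_occ <- sum(ev1$table$landmark == nm)
  expect_equal(ev1$per_landmark$mean_error_mm[ev1$per_landmark$landmark == nm],
               0.5 / n_occ)
})

test_that("success rate counts inclusively at the boundary", {
  expect_equal(successRate(c(0.5, 1.5, 2.5), 2.0), 2 / 3)
  expect_equal(successRate(rep(0, 7), 0.1), 1)
  expect_equal(successRate(c(2.0, 2.0000001), 2.0), 0.5)
  expect_error(successRate(numeric(0), 2))
})

test_that("AUC-CED matches dense numerical integration of the piecewise CED", {
  th <- c(2, 2.5, 3, 4)
  for (k in 1:20) {
    sr <- sort(withr::with_seed(k, runif(4)))
    a <- aucCED(sr, th)
    # dense Riemann sum over the piecewise-linear CED
    grid <- seq(2, 4, length.out = 200001)
    dense <- approx(th, sr, xout = grid)$y
    riemann <- mean(dense[-1] + dense[-length(dense)]) / 2 * (4 - 2)
    expect_equal(a, riemann, tolerance = 1e-9)
  }
  expect_equal(aucCED(rep(1, 4), th), 2.0)
  expect_error(aucCED(0.5, 2))
  expect_error(aucCED(c(0.5, 0.6), c(3, 2)))
})

test_that("compound uncertainty accumulates in quadrature", {
  expect_equal(compoundUncertainty(0, 1.3), 1.3)
  expect_equal(compoundUncertainty(3, 4), 5)
  expect_equal(round(compoundUncertainty(0.54, 0.54), 2), 0.76)
})
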