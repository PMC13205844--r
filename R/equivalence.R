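#' @include AllClasses.R
NULL

#' Two one-sided tests (TOST) of equivalence
#'
#' Tests whether the mean difference between methods lies inside a
#' prespecified symmetric margin: one-sided t-tests of mean > -margin and
#' mean < +margin; `p_tost` is the larger of the two and equivalence is
#' declared when `p_tost < alpha`. Applied to per-landmark Euclidean errors
#' (all nonnegative), the lower test is trivially significant; this mirrors
#' agreement reporting where the bias equals the mean error.
#'
#' Zero-variance data are degenerate: equivalent iff `|mean| < margin`, with
#' `p_tost` 0 or 1 accordingly and the `degenerate` flag set.
#'
#' @param differences_mm Numeric vector (n >= 2) of differences (or error
#'   magnitudes) in mm.
#' @param margin_mm Equivalence margin (clinical default 2.0 mm, symmetric).
#' @param alpha Significance level (default 0.05).
#' @return List of class `"tost"` with `mean`, `sd`, `n`, `p_lower`,
#'   `p_upper`, `p_tost`, `equivalent`, `margin_mm`, `alpha`, `degenerate`.
#' @examples
#' tostEquivalence(rnorm(30, 0.5, 0.3), margin_mm = 2)
#' @export
tostEquivalence <- function(differences_mm, margin_mm = 2.0, alpha = 0.05) {
  .stop_if(length(differences_mm) < 2, "need n >= 2")
  .stop_if(margin_mm <= 0, "margin must be positive")
  n <- length(differences_mm)
  m <- mean(differences_mm)
  s <- sd(differences_mm)
  if (s == 0) {
    eq <- abs(m) < margin_mm
    p <- if (eq) 0 else 1
    return(structure(list(mean = m, sd = s, n = n, p_lower = p, p_upper = p,
                          p_tost = p, equivalent = eq, margin_mm = margin_mm,
                          alpha = alpha, degenerate = TRUE), class = "tost"))
  }
  se <- s / sqrt(n)
  df <- n - 1
  t_lower <- (m + margin_mm) / se   # H1: mean > -margin
  t_upper <- (m - margin_mm) / se   # H1: mean < +margin
  p_lower <- pt(t_lower, df, lower.tail = FALSE)
  p_upper <- pt(t_upper, df, lower.tail = TRUE)
  p_tost <- max(p_lower, p_upper)
  structure(list(mean = m, sd = s, n = n, p_lower = p_lower,
                 p_upper = p_upper, p_tost = p_tost,
                 equivalent = p_tost < alpha, margin_mm = margin_mm,
                 alpha = alpha, degenerate = FALSE), class = "tost")
}

#' @export
print.tost <- function(x, ...) {
  cat(sprintf("TOST equivalence at +/-%.2f mm: mean %.4f, SD %.4f, n %d\n",
              x$margin_mm, x$mean, x$sd, x$n))
  cat(sprintf("  p_tost = %.3g -> %sequivalent at alpha = %.2f%s\n",
              x$p_tost, if (x$equivalent) "" else "NOT ", x$alpha,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference) and 95% limits of agreement
#' `bias +/- 1.96 * SD` (sample SD, n - 1 denominator; 1.96 used verbatim).
#'
#' @param differences_mm Numeric vector (n >= 2) of differences in mm.
#' @return List of class `"bland_altman"` with `bias_mm`, `sd_mm`,
#'   `loa_lower`, `loa_upper`, `n`.
#' @export
blandAltman <- function(differences_mm) {
  .stop_if(length(differences_mm) < 2, "need n >= 2")
  lim <- agreementLimits(mean(differences_mm), sd(differences_mm))
  structure(c(lim, list(n = length(differences_mm))),
            class = "bland_altman")
}

#' Limits of agreement from summary statistics
#'
#' @param bias_mm Mean difference in mm.
#' @param sd_mm SD of the differences in mm.
#' @param multiplier Coverage multiplier (1.96 for 95% limits).
#' @return List with `bias_mm`, `sd_mm`, `loa_lower`, `loa_upper`.
#' @examples
#' agreementLimits(0.5385, 0.6914)  # limits -0.817 and 1.894
#' @export
agreementLimits <- function(bias_mm, sd_mm, multiplier = 1.96) {
  .stop_if(sd_mm < 0, "sd must be nonnegative")
  list(bias_mm = bias_mm, sd_mm = sd_mm,
       loa_lower = bias_mm - multiplier * sd_mm,
       loa_upper = bias_mm + multiplier * sd_mm)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f mm, 95%% LoA %.3f to %.3f mm (n %d)\n",
              x$bias_mm, x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' Intraclass correlation for intra-observer agreement
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC --
#' ICC(2,1) in the Shrout-Fleiss taxonomy -- computed from the standard mean
#' squares of the subject-by-rater two-way layout. This is the conventional
#' form for intra-observer repeatability across two annotation rounds.
#'
#' @param round1,round2 Equal-length paired measurement vectors (n >= 2
#'   subjects).
#' @return List of class `"icc"` with `icc`, `form`, `n_subjects`,
#'   `n_rounds`.
#' @examples
#' x <- rnorm(20); iccIntraObserver(x, x)$icc  # 1
#' @export
iccIntraObserver <- function(round1, round2) {
  .stop_if(length(round1) != length(round2), "rounds must be paired")
  n <- length(round1)
  .stop_if(n < 2, "need at least two subjects")
  Y <- cbind(round1, round2)
  k <- 2L
  grand <- mean(Y)
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((Y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom == 0) 1 else (msr - mse) / denom
  structure(list(icc = icc,
                 form = "ICC(2,1) two-way random, absolute agreement, single measurement",
                 n_subjects = n, n_rounds = k), class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC = %.3f [%s; n = %d, rounds = %d]\n", x$icc, x$form,
              x$n_subjects, x$n_rounds))
  invisible(x)
}

#' Full equivalence report for a set of errors
#'
#' TOST at the clinical margin plus Bland-Altman bias and limits, the
#' standard per-view row of an equivalence table.
#'
#' @param errors_mm Per-prediction error magnitudes in mm.
#' @param margin_mm Equivalence margin (default 2.0 mm).
#' @param alpha Significance level.
#' @return List with `tost` and `bland_altman` components.
#' @export
equivalenceReport <- function(errors_mm, margin_mm = 2.0, alpha = 0.05) {
  list(tost = tostEquivalence(errors_mm, margin_mm, alpha),
       bland_altman = blandAltman(errors_mm))
}
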