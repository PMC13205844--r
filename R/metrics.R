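#' @include AllClasses.R
NULL

#' Euclidean landmark error in millimetres
#'
#' `error_mm = sqrt((x_true - x_pred)^2 + (y_true - y_pred)^2) * scale`,
#' computed in original-resolution pixel space with the fixed export scale
#' (0.1 mm/pixel by default).
#'
#' @param p_true,p_pred Numeric `(x, y)` pairs, or two-column matrices.
#' @param scale Millimetres per pixel.
#' @return Error(s) in mm.
#' @examples
#' pxErrorToMm(c(100, 100), c(103, 104), 0.1)  # 0.5 mm
#' @export
pxErrorToMm <- function(p_true, p_pred, scale = 0.1) {
  .stop_if(scale <= 0, "scale must be positive")
  pt <- matrix(p_true, ncol = 2)
  pp <- matrix(p_pred, ncol = 2)
  sqrt(rowSums((pt - pp)^2)) * scale
}

#' Effective scale of a resized image
#'
#' The mm/pixel ratio after resizing an image of `original_width` pixels to
#' the standardized network resolution: `original_width / normalized_width *
#' base`.
#'
#' @param original_width Original width in px.
#' @param normalized_width Network input width (128).
#' @param base Scale at original resolution (0.1 mm/px).
#' @return Effective mm/pixel.
#' @export
effectiveScale <- function(original_width, normalized_width = 128,
                           base = 0.1) {
  .stop_if(any(original_width <= 0) || normalized_width <= 0,
           "widths must be positive")
  original_width / normalized_width * base
}

#' Scale-consistency summary
#'
#' Mean, SD, and coefficient of variation (CV% = 100 * SD / mean) of
#' per-subject effective scales; consistency passes when CV is below 10%.
#'
#' @param scales Numeric vector of mm/pixel values (length >= 2).
#' @return List with `mean`, `sd`, `cv_pct`, `pass`.
#' @export
scaleConsistency <- function(scales) {
  .stop_if(length(scales) < 2, "need at least two scales")
  m <- mean(scales)
  .stop_if(m == 0, "zero mean scale")
  s <- sd(scales)
  cv <- 100 * s / m
  list(mean = m, sd = s, cv_pct = cv, pass = cv < 10)
}

#' One-sample significance test of errors against zero
#'
#' Two-sided one-sample t-test of a landmark's error magnitudes against a
#' zero-error reference. Because Euclidean errors are nonnegative, any
#' accurate-but-imperfect predictor yields small p-values once
#' `mean >> SD/sqrt(n)`; the result carries a `caveat` noting this. Zero
#' variance is degenerate: p = 0 if the common value is nonzero, 1 if zero.
#'
#' @param errors Numeric vector (length >= 2) of error magnitudes.
#' @return List with `t`, `df`, `p_value`, `degenerate`, `caveat`.
#' @export
significanceVsZero <- function(errors) {
  .stop_if(length(errors) < 2, "need at least two errors")
  caveat <- paste("one-sample t of nonnegative error magnitudes vs zero;",
                  "significance is guaranteed for any consistently nonzero",
                  "error and does not imply clinical relevance")
  if (sd(errors) == 0) {
    m <- mean(errors)
    return(list(t = if (m == 0) 0 else Inf, df = length(errors) - 1L,
                p_value = if (m == 0) 1 else 0, degenerate = TRUE,
                caveat = caveat))
  }
  ht <- t.test(errors, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, degenerate = FALSE, caveat = caveat)
}

#' Per-subject, per-landmark error table
#'
#' Matches predictions to ground truth by subject and view, computes
#' Euclidean errors in original pixel space and in mm, and summarizes per
#' landmark (mean error, one-sample p vs zero) plus the overall mean +/- SD.
#'
#' @param truth List of [AnnotatedImage-class] (ground truth).
#' @param predictions Parallel list of `data.frame`s (`name`, `x`, `y`) as
#'   returned by [predictLandmarks()].
#' @param scale mm per pixel at original resolution.
#' @return List with `table` (subject_id, view, landmark, error_px,
#'   error_mm), `per_landmark` (landmark, n, mean_error_mm, p_value),
#'   `overall` (`mean_mm`, `sd_mm`, `n`).
#' @export
perLandmarkErrors <- function(truth, predictions, scale = 0.1) {
  .stop_if(length(truth) != length(predictions),
           "truth and predictions must be parallel lists")
  rows <- lapply(seq_along(truth), function(i) {
    tl <- landmarks(truth[[i]])
    pl <- predictions[[i]]
    if (!identical(tl$name, pl$name))
      stop(sprintf("landmark mismatch for subject %s",
                   subjectId(truth[[i]])), call. = FALSE)
    err_px <- sqrt((tl$x - pl$x)^2 + (tl$y - pl$y)^2)
    data.frame(subject_id = subjectId(truth[[i]]),
               view = imageView(truth[[i]]), landmark = tl$name,
               error_px = err_px, error_mm = err_px * scale)
  })
  tab <- do.call(rbind, rows)
  schema_order <- unique(tab$landmark)
  per <- do.call(rbind, lapply(schema_order, function(nm) {
    e <- tab$error_mm[tab$landmark == nm]
    p <- if (length(e) >= 2) significanceVsZero(e)$p_value else NA_real_
    data.frame(landmark = nm, n = length(e), mean_error_mm = mean(e),
               p_value = p)
  }))
  list(table = tab, per_landmark = per,
       overall = list(mean_mm = mean(tab$error_mm),
                      sd_mm = sd(tab$error_mm), n = nrow(tab)))
}

#' Success rate at an error threshold
#'
#' Fraction of predictions with error less than or equal to the threshold
#' (boundary inclusive).
#'
#' @param errors_mm Nonempty numeric vector of errors in mm.
#' @param threshold_mm Positive threshold (clinical default 2.0 mm).
#' @return Fraction in `[0, 1]`.
#' @export
successRate <- function(errors_mm, threshold_mm = 2.0) {
  .stop_if(length(errors_mm) == 0, "empty error list")
  .stop_if(threshold_mm <= 0, "threshold must be positive")
  mean(errors_mm <= threshold_mm)
}

#' Area under the cumulative error distribution
#'
#' Trapezoidal integration of success rates over the stated thresholds
#' (default 2, 2.5, 3, 4 mm); no extrapolation below the first threshold.
#' With rates at most 1 the value is bounded by the threshold-range width
#' (2.0 for the default grid).
#'
#' @param success_rates Fractions in `[0, 1]` at the thresholds.
#' @param thresholds Strictly increasing positive thresholds (>= 2 values).
#' @return The trapezoid value (unrounded; conventionally displayed to two
#'   decimals).
#' @examples
#' aucCED(c(0.9796, 0.9859, 0.9859, 0.9890))  # 1.97 to two decimals
#' @export
aucCED <- function(success_rates, thresholds = c(2, 2.5, 3, 4)) {
  .stop_if(length(thresholds) < 2, "need at least two thresholds")
  .stop_if(any(diff(thresholds) <= 0), "thresholds must be increasing")
  .stop_if(length(success_rates) != length(thresholds),
           "one success rate per threshold")
  .stop_if(any(success_rates < 0 | success_rates > 1),
           "success rates must be in [0, 1]")
  sum(diff(thresholds) *
        (head(success_rates, -1) + utils::tail(success_rates, -1)) / 2)
}

#' Cumulative error distribution summary
#'
#' Success rates at each threshold plus the AUC-CED.
#'
#' @param errors_mm Errors in mm.
#' @param thresholds Threshold grid (default `c(2, 2.5, 3, 4)` mm).
#' @param clinical_threshold Highlighted clinical threshold (2.0 mm).
#' @return List with `thresholds`, `success_rates`, `auc_ced`,
#'   `clinical_threshold`, `sr_clinical`.
#' @export
cedCurve <- function(errors_mm, thresholds = c(2, 2.5, 3, 4),
                     clinical_threshold = 2.0) {
  sr <- vapply(thresholds, function(th) successRate(errors_mm, th), 0)
  list(thresholds = thresholds, success_rates = sr,
       auc_ced = aucCED(sr, thresholds),
       clinical_threshold = clinical_threshold,
       sr_clinical = successRate(errors_mm, clinical_threshold))
}

#' Compound uncertainty of a two-landmark measurement
#'
#' Root-sum-of-squares accumulation: a distance measured between two
#' landmarks with individual errors `e1` and `e2` carries
#' `sqrt(e1^2 + e2^2)` combined uncertainty.
#'
#' @param e1,e2 Nonnegative errors in mm.
#' @return Combined uncertainty in mm.
#' @examples
#' compoundUncertainty(0.54, 0.54)  # 0.76 to two decimals
#' @export
compoundUncertainty <- function(e1, e2) {
  .stop_if(any(e1 < 0) || any(e2 < 0), "errors must be nonnegative")
  sqrt(e1^2 + e2^2)
}
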