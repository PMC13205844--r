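#' @include AllClasses.R
NULL

#' Split subjects into training, validation, and test sets
#'
#' Uniformly random subject-level partition, deterministic in `seed`. All
#' images of a subject always land in the same set, which is what prevents
#' identity leakage between training and evaluation.
#'
#' @param subject_ids Character vector of subject ids.
#' @param sizes Integer triple `(train, val, test)`; must sum to
#'   `length(subject_ids)`. The study cohort used `c(68, 15, 15)`.
#' @param seed Integer seed.
#' @return A [CohortSplit-class].
#' @examples
#' subjectSplit(sprintf("S%03d", 1:98), c(68, 15, 15), seed = 42)
#' @export
subjectSplit <- function(subject_ids, sizes = c(68L, 15L, 15L), seed = 42L) {
  subject_ids <- unique(as.character(subject_ids))
  if (sum(sizes) != length(subject_ids))
    stop(sprintf("split sizes sum to %d but there are %d subjects",
                 sum(sizes), length(subject_ids)), call. = FALSE)
  perm <- .with_seed(seed, sample(subject_ids))
  new("CohortSplit",
      trainIds = perm[seq_len(sizes[1])],
      valIds = perm[sizes[1] + seq_len(sizes[2])],
      testIds = perm[sizes[1] + sizes[2] + seq_len(sizes[3])],
      seed = as.integer(seed))
}

#' Check a split for subject leakage
#'
#' Fails iff any subject id appears in more than one set or any image's
#' subject is unassigned.
#'
#' @param split A [CohortSplit-class].
#' @param images List of [AnnotatedImage-class] (the cohort).
#' @return List with `pass` (logical) and `problems` (character vector
#'   naming offending subject ids).
#' @export
assertNoLeakage <- function(split, images) {
  problems <- character()
  sets <- splitSets(split)
  all_assigned <- unlist(sets, use.names = FALSE)
  dup <- unique(all_assigned[duplicated(all_assigned)])
  if (length(dup))
    problems <- c(problems,
                  sprintf("subject %s assigned to multiple sets", dup))
  img_subj <- unique(vapply(images, subjectId, ""))
  unassigned <- setdiff(img_subj, all_assigned)
  if (length(unassigned))
    problems <- c(problems, sprintf("subject %s unassigned", unassigned))
  list(pass = length(problems) == 0L, problems = problems)
}

#' Augmentation configuration
#'
#' Photometric (brightness) augmentation settings: each training image gains
#' `copies_per_image` jittered copies with multiplicative brightness factors
#' drawn uniformly from `[brightness_low, brightness_high]`.
#'
#' @param brightness_low,brightness_high Factor range (defaults 0.7 and 1.3).
#' @param copies_per_image Copies per training image (default 1, which
#'   doubles the training set).
#' @param seed Seed for the factor draws.
#' @return A list of class `"augmentation_config"`.
#' @export
augmentationConfig <- function(brightness_low = 0.7, brightness_high = 1.3,
                               copies_per_image = 1L, seed = 42L) {
  .stop_if(brightness_low <= 0 || brightness_low > brightness_high,
           "need 0 < brightness_low <= brightness_high")
  structure(list(brightness_low = brightness_low,
                 brightness_high = brightness_high,
                 copies_per_image = as.integer(copies_per_image),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Brightness-jitter an image
#'
#' Multiplies every channel value by `factor` and clips to the 8-bit range.
#' Purely photometric: landmarks are untouched.
#'
#' @param img An [AnnotatedImage-class].
#' @param factor Positive brightness factor.
#' @return The jittered [AnnotatedImage-class].
#' @export
brightnessJitter <- function(img, factor) {
  .stop_if(factor <= 0, "factor must be positive")
  px <- pixelArray(img) * factor
  annotatedImage(img@subjectId, img@view, px, img@landmarks,
                 sourcePath = img@sourcePath)
}

#' Augment a training image set
#'
#' Returns the originals followed by `copies_per_image` brightness-jittered
#' copies of each, with factors drawn per copy; deterministic in `cfg$seed`.
#' Never apply this to validation or test images.
#'
#' @param images List of training [AnnotatedImage-class].
#' @param cfg An [augmentationConfig()].
#' @return List of `length(images) * (1 + copies_per_image)` images.
#' @export
augmentTrainingSet <- function(images, cfg = augmentationConfig()) {
  n <- length(images)
  k <- cfg$copies_per_image
  if (k == 0L) return(images)
  factors <- .with_seed(cfg$seed,
                        runif(n * k, cfg$brightness_low, cfg$brightness_high))
  copies <- vector("list", n * k)
  for (i in seq_len(n))
    for (j in seq_len(k))
      copies[[(i - 1L) * k + j]] <- brightnessJitter(images[[i]],
                                                     factors[(i - 1L) * k + j])
  c(images, copies)
}

#' Preprocess an image into a training sample
#'
#' Bilinear resize to 128 x 128 x 3, intensities scaled to `[0, 1]`, and
#' landmark targets normalized to `(x / width, y / height)` pairs interleaved
#' in schema order (length 44 frontal / 30 profile).
#'
#' @param img An [AnnotatedImage-class].
#' @return List of class `"preprocessed_sample"` with elements `input`
#'   (128 x 128 x 3 array), `target`, `subject_id`, `view`, `width`,
#'   `height`.
#' @export
resizeNormalize <- function(img) {
  px <- pixelArray(img) / 255
  eb <- EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color")
  rs <- EBImage::resize(eb, w = 128, h = 128, filter = "bilinear")
  input <- aperm(EBImage::imageData(rs), c(2, 1, 3))
  input <- pmin(pmax(input, 0), 1)
  lm <- img@landmarks
  target <- as.vector(rbind(lm$x / img@width, lm$y / img@height))
  structure(list(input = input, target = target,
                 subject_id = img@subjectId, view = img@view,
                 width = img@width, height = img@height),
            class = "preprocessed_sample")
}

#' Invert coordinate normalization
#'
#' Maps a normalized target vector back to pixel coordinates:
#' `x = u * width`, `y = v * height`.
#'
#' @param vec Even-length numeric vector of interleaved `(u, v)` pairs.
#' @param width,height Original image dimensions in pixels.
#' @param schema Optional [LandmarkSchema-class] used to name the points.
#' @return `data.frame` with columns `name` (if schema given), `x`, `y`.
#' @export
denormalizeLandmarks <- function(vec, width, height, schema = NULL) {
  .stop_if(length(vec) %% 2L != 0L, "target vector must have even length")
  .stop_if(width <= 0 || height <= 0, "dimensions must be positive")
  m <- matrix(vec, nrow = 2L)
  out <- data.frame(x = m[1, ] * width, y = m[2, ] * height)
  if (!is.null(schema)) {
    stopifnot(length(schema@names) * 2L == length(vec))
    out <- cbind(data.frame(name = schema@names), out)
  }
  out
}

# Stack preprocessed samples into the dense arrays consumed by the network:
# X is (3*128*128) x N with channel-fastest pixel order, Y is out_dim x N.
.pack_samples <- function(samples) {
  stopifnot(length(samples) > 0)
  X <- vapply(samples, function(s) as.vector(aperm(s$input, c(3, 1, 2))),
              numeric(3 * 128 * 128))
  Y <- vapply(samples, function(s) s$target,
              numeric(length(samples[[1]]$target)))
  list(X = X, Y = Y)
}

# Images belonging to a set of subject ids, optionally one view only.
.filter_images <- function(images, ids, view = NULL) {
  keep <- vapply(images, function(im) {
    subjectId(im) %in% ids && (is.null(view) || imageView(im) == view)
  }, TRUE)
  images[keep]
}
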