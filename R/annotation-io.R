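#' @include AllClasses.R
NULL

# Resolve a label to its schema abbreviation; full anatomical names are
# accepted as aliases.
.canonical_label <- function(label) {
  if (label %in% names(.NAME_ALIASES)) unname(.NAME_ALIASES[label]) else label
}

.read_image_array <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3]
  aperm(a, c(2, 1, 3)) * 255  # EBImage is (x, y, c); we use (row, col, c)
}

#' Read a LabelMe-style point annotation file
#'
#' Parses the LabelMe JSON dialect (top-level `imagePath`, `imageHeight`,
#' `imageWidth`, and `shapes` with one `point` per named landmark), reorders
#' the landmarks to schema order regardless of file order, and loads the
#' referenced image. Unknown extra labels are ignored with a warning; missing
#' or duplicated schema landmarks, and non-point shapes for schema landmarks,
#' are errors.
#'
#' @param path Path to the JSON file.
#' @param schema A [LandmarkSchema-class]; defaults to the view inferred from
#'   the landmark count is not attempted -- pass the schema explicitly.
#' @param subject_id Optional subject id; defaults to the file stem.
#' @param read_pixels If `FALSE`, a zero image of the declared size is
#'   attached instead of reading `imagePath` (annotation-only use).
#' @return An [AnnotatedImage-class].
#' @export
readLabelmeJSON <- function(path, schema, subject_id = NULL,
                            read_pixels = TRUE) {
  .stop_if(!file.exists(path), sprintf("no such file: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .stop_if(is.null(doc$shapes), "not a LabelMe annotation: no 'shapes'")
  labels <- character(); xs <- numeric(); ys <- numeric()
  for (sh in doc$shapes) {
    lab <- .canonical_label(as.character(sh$label))
    if (!lab %in% schema@names) {
      warning(sprintf("ignoring unknown label '%s'", sh$label), call. = FALSE)
      next
    }
    if (!identical(sh$shape_type, "point") || length(sh$points) != 1L)
      stop(sprintf("landmark '%s' is not a single point", lab), call. = FALSE)
    if (lab %in% labels)
      stop(sprintf("duplicate landmark '%s'", lab), call. = FALSE)
    labels <- c(labels, lab)
    xs <- c(xs, as.numeric(sh$points[[1]][[1]]))
    ys <- c(ys, as.numeric(sh$points[[1]][[2]]))
  }
  missing <- setdiff(schema@names, labels)
  if (length(missing))
    stop(sprintf("missing landmark(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  ord <- match(schema@names, labels)
  lm <- data.frame(name = schema@names, x = xs[ord], y = ys[ord])
  h <- as.integer(doc$imageHeight); w <- as.integer(doc$imageWidth)
  if (read_pixels) {
    img_path <- file.path(dirname(path), doc$imagePath)
    .stop_if(!file.exists(img_path),
             sprintf("referenced image not found: %s", img_path))
    px <- .read_image_array(img_path)
    h <- dim(px)[1]; w <- dim(px)[2]
  } else {
    px <- array(0, dim = c(h, w, 3))
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  annotatedImage(subject_id, schema@view, px, lm, sourcePath = path)
}

#' Write a LabelMe-style point annotation file
#'
#' Emits the dialect with top-level fields `version`, `imagePath`,
#' `imageHeight`, `imageWidth` and `shapes` = list of
#' `{label, points = [[x, y]], shape_type = "point"}`, in schema order with a
#' fixed float format, so the output is byte-deterministic.
#'
#' @param img An [AnnotatedImage-class].
#' @param path Output path.
#' @param image_path Value for the `imagePath` field; defaults to the source
#'   image basename or `<subject>_<view>.png`.
#' @return Invisibly, `path`.
#' @export
writeLabelmeJSON <- function(img, path, image_path = NULL) {
  if (is.null(image_path)) {
    image_path <- if (nzchar(img@sourcePath)) basename(img@sourcePath)
                  else sprintf("%s_%s.png", img@subjectId, img@view)
  }
  shapes <- lapply(seq_len(nrow(img@landmarks)), function(i) {
    list(label = img@landmarks$name[i],
         points = list(c(img@landmarks$x[i], img@landmarks$y[i])),
         group_id = NULL, shape_type = "point",
         flags = structure(list(), names = character(0)))
  })
  doc <- list(version = "5.0.1",
              flags = structure(list(), names = character(0)),
              shapes = shapes,
              imagePath = image_path, imageData = NULL,
              imageHeight = img@height, imageWidth = img@width)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = 2)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Validate an annotated image
#'
#' Quality-control check used as the cohort gate: returns an empty character
#' vector iff the annotation is schema-complete and ordered, all coordinates
#' are finite and strictly inside the image bounds, and the pixel array
#' matches the declared dimensions. Violations are returned as data, not
#' raised.
#'
#' @param img An [AnnotatedImage-class].
#' @return Character vector of violation messages (empty if clean).
#' @export
validateAnnotation <- function(img) {
  v <- character()
  schema <- landmarkSchema(img@view)
  lm <- img@landmarks
  if (!identical(lm$name, schema@names)) {
    missing <- setdiff(schema@names, lm$name)
    extra <- setdiff(lm$name, schema@names)
    if (length(missing))
      v <- c(v, sprintf("missing landmark(s): %s",
                        paste(missing, collapse = ", ")))
    if (length(extra))
      v <- c(v, sprintf("unknown landmark(s): %s",
                        paste(extra, collapse = ", ")))
    if (!length(missing) && !length(extra))
      v <- c(v, "landmarks out of schema order")
  }
  bad <- !is.finite(lm$x) | !is.finite(lm$y)
  if (any(bad))
    v <- c(v, sprintf("non-finite coordinates: %s",
                      paste(lm$name[bad], collapse = ", ")))
  oob <- !bad & (lm$x < 0 | lm$x >= img@width | lm$y < 0 |
                   lm$y >= img@height)
  if (any(oob))
    v <- c(v, sprintf("out-of-bounds landmark(s): %s",
                      paste(lm$name[oob], collapse = ", ")))
  d <- dim(img@pixels)
  if (d[1] != img@height || d[2] != img@width)
    v <- c(v, "pixel array does not match declared dimensions")
  v
}

#' Quality-control gate over a cohort
#'
#' Drops every subject any of whose images fails [validateAnnotation()],
#' mirroring the exclusion of incomplete, missing, or distorted images during
#' cohort assembly.
#'
#' @param images List of [AnnotatedImage-class].
#' @return List with `images` (survivors), `dropped` (subject ids), and
#'   `violations` (named list per dropped subject).
#' @export
qcGate <- function(images) {
  subj <- vapply(images, subjectId, "")
  viol <- lapply(images, validateAnnotation)
  bad_img <- lengths(viol) > 0
  dropped <- unique(subj[bad_img])
  keep <- !subj %in% dropped
  report <- list()
  for (s in dropped)
    report[[s]] <- unlist(viol[subj == s], use.names = FALSE)
  list(images = images[keep], dropped = dropped, violations = report)
}
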