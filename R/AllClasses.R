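#' @include utils.R
NULL

.FRONTAL_NAMES <- c("Tr", "G", "N", "Prn", "Sn", "Phi", "Ls", "Stm", "Li",
                    "Pg", "Gn", "Me", "GoL", "GoR", "ChR", "ChL", "AlL",
                    "AlR", "ExL", "ExR", "EndR", "EndL")
.PROFILE_NAMES <- c("Tr", "G", "N", "Prn", "Col", "Al", "Sn", "Phi", "Ls",
                    "Stm", "Li", "Pg", "Gn", "Me", "Go")
.MIDLINE_NAMES <- c("Tr", "G", "N", "Prn", "Sn", "Phi", "Ls", "Stm", "Li",
                    "Pg", "Gn", "Me")

# Full anatomical names accepted as aliases in annotation files.
.NAME_ALIASES <- c(
  "Trichion" = "Tr", "Glabella" = "G", "Nasion" = "N", "Pronasale" = "Prn",
  "Columella" = "Col", "Subnasale" = "Sn", "Philtrum" = "Phi",
  "Labium Superior" = "Ls", "LabiumSuperior" = "Ls", "Stomion" = "Stm",
  "Labium Inferior" = "Li", "LabiumInferior" = "Li", "Pogonion" = "Pg",
  "Gnathion" = "Gn", "Menton" = "Me", "Gonion" = "Go",
  "Gonion Left" = "GoL", "GonionLeft" = "GoL",
  "Gonion Right" = "GoR", "GonionRight" = "GoR",
  "Chelion Left" = "ChL", "ChelionLeft" = "ChL",
  "Chelion Right" = "ChR", "ChelionRight" = "ChR",
  "Alare Left" = "AlL", "AlareLeft" = "AlL",
  "Alare Right" = "AlR", "AlareRight" = "AlR", "Alare" = "Al",
  "Exocanthion Left" = "ExL", "ExocanthionLeft" = "ExL",
  "Exocanthion Right" = "ExR", "ExocanthionRight" = "ExR",
  "Endocanthion Left" = "EndL", "EndocanthionLeft" = "EndL",
  "Endocanthion Right" = "EndR", "EndocanthionRight" = "EndR")

#' Landmark schema for a view
#'
#' An ordered, named list of soft-tissue landmarks defining one view:
#' 22 landmarks for the frontal view, 15 for the profile view. The ordering is
#' fixed and shared by annotation files, model outputs, and error tables.
#'
#' @slot view `"frontal"` or `"profile"`.
#' @slot names Ordered character vector of landmark abbreviations.
#' @export
setClass("LandmarkSchema",
         representation(view = "character", names = "character"))

setValidity("LandmarkSchema", function(object) {
  msg <- character()
  if (!object@view %in% c("frontal", "profile"))
    msg <- c(msg, "view must be 'frontal' or 'profile'")
  expected <- if (identical(object@view, "frontal")) 22L else 15L
  if (length(object@names) != expected)
    msg <- c(msg, sprintf("%s schema must have %d landmarks, found %d",
                          object@view, expected, length(object@names)))
  if (anyDuplicated(object@names))
    msg <- c(msg, "landmark names must be unique")
  if (length(msg)) msg else TRUE
})

#' @param view `"frontal"` or `"profile"`.
#' @return A [LandmarkSchema-class] object.
#' @rdname LandmarkSchema-class
#' @examples
#' landmarkSchema("frontal")
#' @export
landmarkSchema <- function(view = c("frontal", "profile")) {
  view <- match.arg(view)
  nm <- if (view == "frontal") .FRONTAL_NAMES else .PROFILE_NAMES
  new("LandmarkSchema", view = view, names = nm)
}

#' Annotated face image
#'
#' One face image together with its ordered, named landmark points and
#' subject/view metadata. Pixels are stored as an 8-bit `H x W x 3` raw array;
#' landmark coordinates are 0-based pixel-center positions with `x` the column
#' (rightward) and `y` the row (downward), matching the LabelMe convention.
#'
#' @slot subjectId Subject identifier; both views of a subject share it.
#' @slot view `"frontal"` or `"profile"`.
#' @slot pixels `H x W x 3` raw array of 8-bit intensities.
#' @slot width,height Image dimensions in pixels.
#' @slot landmarks `data.frame` with columns `name`, `x`, `y` in schema order.
#' @slot sourcePath Path the image was read from, or `""`.
#' @export
setClass("AnnotatedImage",
         representation(subjectId = "character", view = "character",
                        pixels = "array", width = "integer",
                        height = "integer", landmarks = "data.frame",
                        sourcePath = "character"))

setValidity("AnnotatedImage", function(object) {
  msg <- character()
  if (!object@view %in% c("frontal", "profile"))
    msg <- c(msg, "view must be 'frontal' or 'profile'")
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "pixels must be an H x W x 3 array")
  else if (d[1] != object@height || d[2] != object@width)
    msg <- c(msg, "pixel array dimensions must match height/width")
  lm <- object@landmarks
  if (!all(c("name", "x", "y") %in% names(lm)))
    msg <- c(msg, "landmarks must have columns name, x, y")
  if (length(msg)) msg else TRUE
})

#' @describeIn AnnotatedImage-class Construct an annotated image.
#' @param subjectId,view,pixels,landmarks,sourcePath See slots.
#' @export
annotatedImage <- function(subjectId, view, pixels, landmarks,
                           sourcePath = "") {
  if (is.numeric(pixels)) {
    d <- dim(pixels)
    pixels <- array(.to_u8_cpp(pixels), dim = d)
  }
  d <- dim(pixels)
  new("AnnotatedImage", subjectId = as.character(subjectId), view = view,
      pixels = pixels, width = as.integer(d[2]), height = as.integer(d[1]),
      landmarks = landmarks, sourcePath = sourcePath)
}

#' Subject-level cohort split
#'
#' A partition of subject identifiers into training, validation, and test
#' sets. Splitting is keyed on subjects, never on images, so both views of a
#' subject always travel together.
#'
#' @slot trainIds,valIds,testIds Disjoint subject-id vectors.
#' @slot seed The seed that produced the split.
#' @export
setClass("CohortSplit",
         representation(trainIds = "character", valIds = "character",
                        testIds = "character", seed = "integer"))

setValidity("CohortSplit", function(object) {
  all_ids <- c(object@trainIds, object@valIds, object@testIds)
  if (anyDuplicated(all_ids))
    "subject ids must not appear in more than one set" else TRUE
})

#' Coordinate-regression landmark network
#'
#' The fitted (or freshly initialized) convolutional network that regresses
#' normalized landmark coordinates from a 128 x 128 x 3 face image, together
#' with its architecture description, training configuration, and per-epoch
#' loss history.
#'
#' @slot schema The [LandmarkSchema-class] the network predicts.
#' @slot weights List of layer weight matrices (opaque).
#' @slot modelSpec List describing the architecture.
#' @slot trainConfig Training configuration used (empty until trained).
#' @slot history `data.frame` with per-epoch train/validation loss.
#' @slot trained Logical; whether [trainModel()] has been run.
#' @export
setClass("LandmarkNet",
         representation(schema = "LandmarkSchema", weights = "list",
                        modelSpec = "list", trainConfig = "list",
                        history = "data.frame", trained = "logical"))

## ---- accessors ----

#' @rdname AnnotatedImage-class
#' @param object,x An object.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname AnnotatedImage-class
#' @export
setMethod("subjectId", "AnnotatedImage", function(x) x@subjectId)

#' @rdname AnnotatedImage-class
#' @export
setGeneric("imageView", function(x) standardGeneric("imageView"))
#' @rdname AnnotatedImage-class
#' @export
setMethod("imageView", "AnnotatedImage", function(x) x@view)

#' @rdname AnnotatedImage-class
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))
#' @rdname AnnotatedImage-class
#' @export
setMethod("landmarks", "AnnotatedImage", function(x) x@landmarks)

#' @rdname AnnotatedImage-class
#' @export
setGeneric("imageWidth", function(x) standardGeneric("imageWidth"))
#' @rdname AnnotatedImage-class
#' @export
setMethod("imageWidth", "AnnotatedImage", function(x) x@width)

#' @rdname AnnotatedImage-class
#' @export
setGeneric("imageHeight", function(x) standardGeneric("imageHeight"))
#' @rdname AnnotatedImage-class
#' @export
setMethod("imageHeight", "AnnotatedImage", function(x) x@height)

#' @rdname AnnotatedImage-class
#' @details `pixelArray()` returns pixels as a numeric `H x W x 3` array on
#'   the 0--255 scale.
#' @export
setGeneric("pixelArray", function(x) standardGeneric("pixelArray"))
#' @rdname AnnotatedImage-class
#' @export
setMethod("pixelArray", "AnnotatedImage", function(x) {
  array(as.integer(x@pixels), dim = dim(x@pixels))
})

#' @rdname LandmarkSchema-class
#' @param x An object.
#' @export
setGeneric("landmarkNames", function(x) standardGeneric("landmarkNames"))
#' @rdname LandmarkSchema-class
#' @export
setMethod("landmarkNames", "LandmarkSchema", function(x) x@names)
#' @rdname LandmarkSchema-class
#' @export
setMethod("landmarkNames", "AnnotatedImage", function(x) x@landmarks$name)

#' @rdname CohortSplit-class
#' @param x A [CohortSplit-class].
#' @export
setGeneric("splitSets", function(x) standardGeneric("splitSets"))
#' @rdname CohortSplit-class
#' @export
setMethod("splitSets", "CohortSplit", function(x) {
  list(train = x@trainIds, val = x@valIds, test = x@testIds)
})

## ---- show methods ----

setMethod("show", "LandmarkSchema", function(object) {
  cat(sprintf("LandmarkSchema: %s view, %d landmarks\n", object@view,
              length(object@names)))
  cat("  ", paste(object@names, collapse = " "), "\n")
})

setMethod("show", "AnnotatedImage", function(object) {
  cat(sprintf("AnnotatedImage: subject %s, %s view, %d x %d px, %d landmarks\n",
              object@subjectId, object@view, object@width, object@height,
              nrow(object@landmarks)))
})

setMethod("show", "CohortSplit", function(object) {
  cat(sprintf("CohortSplit: %d train / %d val / %d test subjects (seed %d)\n",
              length(object@trainIds), length(object@valIds),
              length(object@testIds), object@seed))
})

setMethod("show", "LandmarkNet", function(object) {
  cat(sprintf("LandmarkNet (%s view): %d output units, %s parameters, %s\n",
              object@schema@view, object@modelSpec$output_units,
              format(countParameters(object), big.mark = ","),
              if (object@trained) sprintf("trained (%d epochs)",
                                          nrow(object@history))
              else "untrained"))
})
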