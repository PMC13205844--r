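#' @include AllClasses.R dataset.R
NULL

# Architecture constants: four Conv(3x3, valid, stride 1) + MaxPool(2x2)
# blocks with filter depths 32/64/128/256; spatial trace from 128 is
# 126->63->61->30->28->14->12->6, so the flattened width is 6*6*256 = 9216.
.CONV_FILTERS <- c(32L, 64L, 128L, 256L)
.FLAT_UNITS <- 9216L
.DENSE_UNITS <- 512L

.model_spec <- function(schema) {
  list(input_shape = c(128L, 128L, 3L), conv_filters = .CONV_FILTERS,
       kernel = c(3L, 3L), stride = c(1L, 1L), padding = "valid",
       pool = c(2L, 2L), dense_units = .DENSE_UNITS, dropout_rate = 0.5,
       output_units = 2L * length(schema@names),
       hidden_activation = "relu", output_activation = "sigmoid",
       flatten_units = .FLAT_UNITS)
}

# Glorot-uniform draw for an n_out x n_in weight matrix.
.glorot <- function(n_out, n_in, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(n_out * n_in, -lim, lim), nrow = n_out)
}

#' Build an initialized landmark network
#'
#' Constructs the coordinate-regression architecture for a view: four
#' convolutional blocks (3x3 kernels, valid padding, stride 1, 2x2 max
#' pooling, ReLU) with filter depths 32/64/128/256, a flatten to 9216 units,
#' Dense(512, ReLU), Dropout(0.5), and a sigmoid output of width
#' `2 * n_landmarks` (44 frontal / 30 profile). Weights are Glorot-uniform,
#' seeded; biases start at zero.
#'
#' @param schema A [LandmarkSchema-class].
#' @param init_seed Seed for weight initialization (default 42).
#' @return An untrained [LandmarkNet-class].
#' @examples
#' net <- buildModel(landmarkSchema("profile"))
#' countParameters(net)
#' @export
buildModel <- function(schema, init_seed = 42L) {
  stopifnot(is(schema, "LandmarkSchema"))
  spec <- .model_spec(schema)
  out_units <- spec$output_units
  weights <- .with_seed(init_seed, {
    cin <- c(3L, .CONV_FILTERS[-4])
    w <- list()
    for (l in 1:4) {
      fan_in <- 9L * cin[l]
      fan_out <- 9L * .CONV_FILTERS[l]
      w[[2 * l - 1]] <- .glorot(.CONV_FILTERS[l], 9L * cin[l], fan_in, fan_out)
      w[[2 * l]] <- numeric(.CONV_FILTERS[l])
    }
    w[[9]] <- .glorot(.DENSE_UNITS, .FLAT_UNITS, .FLAT_UNITS, .DENSE_UNITS)
    w[[10]] <- numeric(.DENSE_UNITS)
    w[[11]] <- .glorot(out_units, .DENSE_UNITS, .DENSE_UNITS, out_units)
    w[[12]] <- numeric(out_units)
    w
  })
  new("LandmarkNet", schema = schema, weights = weights, modelSpec = spec,
      trainConfig = list(), history = data.frame(), trained = FALSE)
}

#' Count trainable parameters
#'
#' Layer-by-layer closed-form count: a convolution contributes
#' `(kh * kw * c_in + 1) * c_out`, a dense layer `(n_in + 1) * n_out`.
#'
#' @param x A [LandmarkNet-class] or a model-spec list.
#' @return Integer parameter count (5,130,092 for the frontal head;
#'   5,122,910 for profile).
#' @export
countParameters <- function(x) {
  spec <- if (is(x, "LandmarkNet")) x@modelSpec else x
  cin <- c(spec$input_shape[3], spec$conv_filters[-length(spec$conv_filters)])
  conv <- sum((prod(spec$kernel) * cin + 1) * spec$conv_filters)
  dense <- (spec$flatten_units + 1) * spec$dense_units +
    (spec$dense_units + 1) * spec$output_units
  as.integer(conv + dense)
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 1e-4, mean squared error on normalized coordinates, batch size 16, up to
#' 50 epochs with early stopping on validation loss (patience 10, best
#' weights restored), fixed seeds.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param early_stopping Monitor validation loss and stop early?
#' @param dropout_rate Dropout before the output layer.
#' @param data_seed Seed for epoch shuffling and dropout masks.
#' @param verbose Print per-epoch losses?
#' @return A list of class `"train_config"`.
#' @export
trainConfig <- function(learning_rate = 1e-4, batch_size = 16L,
                        max_epochs = 50L, patience = 10L,
                        early_stopping = TRUE, dropout_rate = 0.5,
                        data_seed = 42L, verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, patience <= max_epochs,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 early_stopping = isTRUE(early_stopping),
                 dropout_rate = dropout_rate,
                 data_seed = as.integer(data_seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train a landmark network
#'
#' Minimizes mean squared error on normalized coordinates with Adam,
#' reshuffling batches each epoch from `data_seed`. With validation samples
#' and early stopping, training halts after `patience` epochs without
#' validation improvement and the best-validation weights are restored.
#'
#' @param net An (untrained or trained) [LandmarkNet-class].
#' @param train_samples,val_samples Lists of [resizeNormalize()] samples;
#'   keep them disjoint by subject.
#' @param config A [trainConfig()].
#' @return The trained [LandmarkNet-class] with per-epoch `history`.
#' @export
trainModel <- function(net, train_samples, val_samples = NULL,
                       config = trainConfig()) {
  .stop_if(length(train_samples) == 0, "empty training set")
  out_units <- net@modelSpec$output_units
  bad <- vapply(train_samples, function(s) length(s$target) != out_units, TRUE)
  .stop_if(any(bad), "sample target length does not match the network view")
  tr <- .pack_samples(train_samples)
  if (length(val_samples)) {
    va <- .pack_samples(val_samples)
  } else {
    va <- list(X = matrix(0, nrow(tr$X), 0), Y = matrix(0, out_units, 0))
  }
  n <- ncol(tr$X)
  orders <- .with_seed(config$data_seed,
                       vapply(seq_len(config$max_epochs),
                              function(e) sample.int(n), integer(n)))
  orders <- matrix(as.integer(orders), nrow = n)
  fit <- .cnn_train_cpp(net@weights, tr$X, tr$Y, va$X, va$Y, orders,
                        config$learning_rate, config$batch_size,
                        config$max_epochs, config$patience,
                        config$dropout_rate,
                        .derive_seed(config$data_seed, 0L, 77L),
                        config$early_stopping, config$verbose)
  hist <- data.frame(epoch = seq_along(fit$train_loss),
                     train_loss = fit$train_loss)
  hist$val_loss <- if (length(fit$val_loss)) fit$val_loss else NA_real_
  net@weights <- fit$weights
  net@history <- hist
  net@trainConfig <- c(unclass(config),
                       list(best_epoch = fit$best_epoch,
                            best_val_loss = fit$best_val_loss))
  net@trained <- TRUE
  net
}

#' Predict normalized coordinates for packed inputs
#'
#' Low-level forward pass (dropout inactive) on an input matrix as produced
#' by the internal sample packer; mostly useful for tests and batch scoring.
#'
#' @param net A [LandmarkNet-class].
#' @param X `(3*128*128) x N` input matrix.
#' @return `out_units x N` matrix of sigmoid outputs in `(0, 1)`.
#' @export
predictNormalized <- function(net, X) {
  .cnn_predict_cpp(net@weights, X)
}

#' Predict landmarks on an image
#'
#' Runs the forward pass (dropout inactive) on the resized, normalized input
#' and denormalizes the sigmoid outputs by the image's original width and
#' height. Repeated calls on the same image are bit-identical.
#'
#' @param net A [LandmarkNet-class].
#' @param img An [AnnotatedImage-class] whose view matches the network.
#' @return `data.frame` with columns `name`, `x`, `y` in original pixel
#'   coordinates.
#' @export
setGeneric("predictLandmarks",
           function(net, img) standardGeneric("predictLandmarks"))

#' @rdname predictLandmarks
#' @export
setMethod("predictLandmarks", signature("LandmarkNet", "AnnotatedImage"),
          function(net, img) {
  if (!identical(imageView(img), net@schema@view))
    stop(sprintf("image view '%s' does not match network view '%s'",
                 imageView(img), net@schema@view), call. = FALSE)
  s <- resizeNormalize(img)
  X <- matrix(as.vector(aperm(s$input, c(3, 1, 2))), ncol = 1)
  p <- .cnn_predict_cpp(net@weights, X)[, 1]
  denormalizeLandmarks(p, img@width, img@height, net@schema)
})
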