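# LeNet-style convolutional classifier: training, prediction, saliency.

#' Architecture description of the convolutional classifier
#'
#' Two convolutional layers (default 16 and 32 filters, 5x5 kernels, stride
#' 1, no padding), each followed by ReLU and 2x2 max pooling, then a fully
#' connected layer (default 64 units) and a 2-class output. Class coding:
#' 0 = delayed, 1 = non-delayed.
#'
#' @param convFilters integer pair of filter counts.
#' @param kernelSize convolution kernel side.
#' @param poolSize pooling window (fixed 2 in this implementation).
#' @param fcUnits hidden fully connected units.
#' @param nClasses number of classes (fixed 2).
#' @param inputResolution square input image side in pixels.
#' @return named list describing the architecture.
#' @export
cnnSpec <- function(convFilters = c(16L, 32L), kernelSize = 5L,
                    poolSize = 2L, fcUnits = 64L, nClasses = 2L,
                    inputResolution = 56L) {
  spec <- list(convFilters = as.integer(convFilters),
               kernelSize = as.integer(kernelSize),
               poolSize = as.integer(poolSize),
               fcUnits = as.integer(fcUnits), nClasses = as.integer(nClasses),
               inputResolution = as.integer(inputResolution))
  if (spec$nClasses != 2L) stop("nClasses is fixed at 2")
  if (spec$poolSize != 2L) stop("poolSize is fixed at 2")
  d <- .cnnDims(spec)
  if (d$p2 < 1L) stop("input resolution too small for two conv/pool stages")
  spec
}

.cnnDims <- function(spec) {
  res <- spec$inputResolution
  k <- spec$kernelSize
  c1 <- res - k + 1L
  p1 <- c1 %/% 2L
  c2 <- p1 - k + 1L
  p2 <- c2 %/% 2L
  list(c1 = c1, p1 = p1, c2 = c2, p2 = p2,
       flat = p2 * p2 * spec$convFilters[2])
}

#' Number of trainable parameters of an architecture
#'
#' Closed-form layer-size arithmetic: with kernel side k, filter counts
#' (F1, F2), hidden units H and flattened size D after the second pool,
#' the count is F1(k^2+1) + F2(F1 k^2 + 1) + H(D + 1) + 2(H + 1).
#'
#' @param spec a [cnnSpec()] list.
#' @return integer parameter count.
#' @examples
#' cnnParameterCount(cnnSpec(inputResolution = 56))
#' @export
cnnParameterCount <- function(spec) {
  k2 <- spec$kernelSize^2
  F1 <- spec$convFilters[1]
  F2 <- spec$convFilters[2]
  d <- .cnnDims(spec)
  F1 * (k2 + 1) + F2 * (F1 * k2 + 1) +
    spec$fcUnits * (d$flat + 1) + spec$nClasses * (spec$fcUnits + 1)
}

#' Training configuration
#'
#' @param epochsMax maximum epochs (default 20).
#' @param batchSize minibatch size (default 32).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param earlyStopPatience epochs without validation-loss improvement
#'   before stopping (default 5); the best-validation weights are kept.
#' @param seed integer seed fixing initialization and batch order.
#' @return named list.
#' @export
trainConfig <- function(epochsMax = 20L, batchSize = 32L,
                        learningRate = 1e-3, earlyStopPatience = 5L,
                        seed = 1L) {
  list(epochsMax = as.integer(epochsMax), batchSize = as.integer(batchSize),
       learningRate = learningRate,
       earlyStopPatience = as.integer(earlyStopPatience),
       seed = as.integer(seed))
}

# He-initialized weights, drawn from R's RNG for seed reproducibility.
.initWeights <- function(spec) {
  k2 <- spec$kernelSize^2
  F1 <- spec$convFilters[1]
  F2 <- spec$convFilters[2]
  d <- .cnnDims(spec)
  he <- function(nout, nin)
    matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
  list(W1 = he(F1, k2), b1 = numeric(F1),
       W2 = he(F2, F1 * k2), b2 = numeric(F2),
       W3 = he(spec$fcUnits, d$flat), b3 = numeric(spec$fcUnits),
       W4 = he(spec$nClasses, spec$fcUnits), b4 = numeric(spec$nClasses))
}

.labelsToClass <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- !labels %in% c("delayed", "non_delayed")
    if (any(bad)) stop("labels must be 'delayed' or 'non_delayed'")
    ifelse(labels == "delayed", 0L, 1L)  # delay = class 0
  } else as.integer(labels)
}

#' Train the convolutional classifier
#'
#' Minimizes two-class cross-entropy with Adam over the architecture
#' described by \code{spec}, with early stopping on validation loss (the
#' weights with the best validation loss are returned). Images are
#' standardized by the mean and standard deviation of the training pixels;
#' those constants are stored in the model and reused at prediction and
#' Grad-CAM time. A fixed seed fixes initialization and batch order, making
#' training reproducible.
#'
#' @param trainImages,valImages lists of [TraceImage-class] at the
#'   resolution in \code{spec}.
#' @param trainLabels,valLabels class labels ("delayed"/"non_delayed", or
#'   integer 0/1 with 0 = delayed).
#' @param spec a [cnnSpec()] list.
#' @param cfg a [trainConfig()] list.
#' @return a trained [CnnModel-class].
#' @export
cnnTrain <- function(trainImages, trainLabels, valImages, valLabels,
                     spec = cnnSpec(), cfg = trainConfig()) {
  y <- .labelsToClass(trainLabels)
  yv <- .labelsToClass(valLabels)
  if (length(unique(y)) < 2L || length(unique(yv)) < 2L)
    stop("both classes must be present in training and validation sets")
  res <- spec$inputResolution
  X <- .imageMatrix(trainImages, res)
  Xv <- .imageMatrix(valImages, res)
  normMean <- mean(X)
  normSd <- sd(as.numeric(X))
  if (normSd == 0) stop("degenerate training images (zero variance)")
  X <- (X - normMean) / normSd
  Xv <- (Xv - normMean) / normSd

  n <- ncol(X)
  init <- withr::with_seed(cfg$seed, .initWeights(spec))
  order <- withr::with_seed(cfg$seed + 1L, {
    vapply(seq_len(cfg$epochsMax), function(e) sample.int(n), integer(n))
  })
  fit <- .cnn_train_cpp(X, y, Xv, yv, init, res, spec$kernelSize,
                        spec$convFilters[1], spec$convFilters[2],
                        spec$fcUnits, spec$nClasses, order,
                        cfg$batchSize, cfg$learningRate,
                        cfg$earlyStopPatience)
  new("CnnModel", spec = spec, weights = fit$weights,
      history = as.data.frame(fit$history),
      normMean = normMean, normSd = normSd, trained = TRUE)
}

#' Predict classes for trace images
#'
#' Applies the trained network; probabilities sum to 1 per image, the label
#' is the argmax, and the score intended for ROC analysis is the
#' probability of the delayed class (class 0).
#'
#' @param model a trained [CnnModel-class].
#' @param images list of [TraceImage-class] at the model's resolution.
#' @return data.frame: event_id, p_delayed, p_non_delayed, label.
#' @export
cnnPredict <- function(model, images) {
  if (!model@trained) stop("model is untrained")
  spec <- model@spec
  X <- .imageMatrix(images, spec$inputResolution)
  X <- (X - model@normMean) / model@normSd
  probs <- .cnn_predict_cpp(model@weights, X, spec$inputResolution,
                            spec$kernelSize, spec$convFilters[1],
                            spec$convFilters[2], spec$fcUnits, spec$nClasses)
  data.frame(
    event_id = vapply(images, eventId, character(1)),
    p_delayed = probs[1, ], p_non_delayed = probs[2, ],
    label = ifelse(probs[1, ] >= probs[2, ], "delayed", "non_delayed"),
    stringsAsFactors = FALSE)
}

#' Classify events with a trained model
#'
#' Convenience wrapper: renders events at the model's resolution and
#' returns calls in the same shape as [classifyMsd()]/[classifySe()]. Score
#' convention: \code{1 - p_delayed}, so that lower scores mean stronger
#' delay evidence, as for the rule classifiers.
#'
#' @param model trained [CnnModel-class].
#' @param events list of [EventTrace-class].
#' @param ... passed to [renderImages()].
#' @return data.frame with one row per event.
#' @export
classifyCnn <- function(model, events, ...) {
  imgs <- renderImages(events, model@spec$inputResolution, ...)
  pred <- cnnPredict(model, imgs)
  data.frame(event_id = pred$event_id, method = "cnn", label = pred$label,
             score = 1 - pred$p_delayed, delay_start_frac = NA_real_,
             run_length = NA_integer_, indeterminate = FALSE,
             stringsAsFactors = FALSE)
}
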