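# Grad-CAM saliency for the convolutional classifier.

#' Saliency heatmap
#'
#' Result of [gradCam()]: a class-discriminative heatmap over the input
#' image, nonnegative by construction (rectified weighted activation sum)
#' and max-normalized to 1 unless identically zero.
#'
#' @slot heatmap numeric resolution x resolution matrix in [0, 1].
#' @slot targetClass 0 (delayed) or 1 (non-delayed).
#' @slot zero TRUE when the rectified map was identically zero (degenerate
#'   gradients); the heatmap is then all zeros.
#' @exportClass Saliency
setClass("Saliency",
  representation(heatmap = "matrix", targetClass = "integer",
                 zero = "logical"))

setMethod("show", "Saliency", function(object) {
  cat("Saliency for class", object@targetClass,
      if (object@zero) "(degenerate: all-zero)" else "", "\n")
  cat("  ", nrow(object@heatmap), "x", ncol(object@heatmap), "px\n")
})

# Bilinear upsampling of a matrix to (rows, cols), pixel-center aligned.
.bilinearUpsample <- function(m, rows, cols) {
  sr <- nrow(m)
  sc <- ncol(m)
  if (sr == rows && sc == cols) return(m)
  # map target pixel centers onto source pixel-center coordinates
  ry <- if (rows > 1) (seq_len(rows) - 0.5) / rows * sr + 0.5 else 1
  rx <- if (cols > 1) (seq_len(cols) - 0.5) / cols * sc + 0.5 else 1
  y0 <- pmin(pmax(floor(ry - 0.5) + 0.5, 0.5), sr - 0.5)
  x0 <- pmin(pmax(floor(rx - 0.5) + 0.5, 0.5), sc - 0.5)
  iy <- pmin(pmax(as.integer(y0 + 0.5), 1L), sr)
  ix <- pmin(pmax(as.integer(x0 + 0.5), 1L), sc)
  fy <- pmin(pmax(ry - y0, 0), 1)
  fx <- pmin(pmax(rx - x0, 0), 1)
  iy1 <- pmin(iy + 1L, sr)
  ix1 <- pmin(ix + 1L, sc)
  out <- matrix(0, rows, cols)
  for (r in seq_len(rows)) {
    a <- m[iy[r], ix] * (1 - fx) + m[iy[r], ix1] * fx
    b <- m[iy1[r], ix] * (1 - fx) + m[iy1[r], ix1] * fx
    out[r, ] <- a * (1 - fy[r]) + b * fy[r]
  }
  out
}

#' Grad-CAM saliency map
#'
#' Computes the gradient of the target-class logit with respect to the
#' activation maps of the last convolutional layer, averages each channel's
#' gradient spatially to obtain channel weights, forms the rectified
#' weighted sum of activations, bilinearly upsamples it to the input
#' resolution, and normalizes to a maximum of 1. Highlights the input
#' regions the classifier relied on; for delayed events the expectation is
#' concentration on the low-variability plateau.
#'
#' @param model a trained [CnnModel-class].
#' @param image a [TraceImage-class] at the model's resolution.
#' @param targetClass 0 (delayed) or 1 (non-delayed).
#' @return a [Saliency-class] object.
#' @export
gradCam <- function(model, image, targetClass) {
  if (!model@trained) stop("model is untrained")
  spec <- model@spec
  targetClass <- as.integer(targetClass)
  if (!targetClass %in% c(0L, 1L)) stop("targetClass must be 0 or 1")
  x <- (as.numeric(imagePixels(image)) - model@normMean) / model@normSd
  if (imageResolution(image) != spec$inputResolution)
    stop("image resolution does not match the model")
  out <- .cnn_gradcam_cpp(model@weights, x, spec$inputResolution,
                          spec$kernelSize, spec$convFilters[1],
                          spec$convFilters[2], spec$fcUnits,
                          spec$nClasses, targetClass)
  act <- out$activations
  grad <- out$gradients
  w <- apply(grad, 3, mean)
  cam <- matrix(0, dim(act)[1], dim(act)[2])
  for (f in seq_along(w)) cam <- cam + w[f] * act[, , f]
  cam[cam < 0] <- 0
  zero <- max(cam) == 0
  heat <- .bilinearUpsample(cam, spec$inputResolution, spec$inputResolution)
  heat[heat < 0] <- 0
  if (!zero && max(heat) > 0) heat <- heat / max(heat)
  new("Saliency", heatmap = heat, targetClass = targetClass, zero = zero)
}

#' Fraction of saliency mass inside a fractional-position band
#'
#' Sums heatmap mass over the columns covering fractional positions
#' \code{[lo, hi]} of the event (time runs along columns), divided by total
#' mass. Under a uniform heatmap this equals \code{hi - lo}; values above
#' that indicate model focus inside the band.
#'
#' @param saliency a [Saliency-class].
#' @param lo,hi fractional position band (defaults 0.7, 1.0 - the delay
#'   region).
#' @return fraction in [0, 1]; NA for an all-zero heatmap.
#' @export
saliencyBandMass <- function(saliency, lo = 0.7, hi = 1.0) {
  h <- saliency@heatmap
  tot <- sum(h)
  if (tot == 0) return(NA_real_)
  nc <- ncol(h)
  cols <- which((seq_len(nc) - 0.5) / nc >= lo & (seq_len(nc) - 0.5) / nc <= hi)
  sum(h[, cols]) / tot
}
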