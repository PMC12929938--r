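# Trace-to-image rendering for the convolutional classifier.

.SUPPORTED_RES <- c(28L, 56L, 70L, 84L, 112L, 140L, 240L)
.MASTER_RES <- 240L

# Area-averaging resampling matrix from `from` to `to` pixels (to <= from).
# Row i holds the fractional overlap of target pixel i with each source
# pixel, normalized to sum 1.
.resampleMatrix <- function(to, from) {
  A <- matrix(0, to, from)
  scale <- from / to
  for (i in seq_len(to)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, from)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) A[i, j] <- ov
    }
    A[i, ] <- A[i, ] / sum(A[i, ])
  }
  A
}

#' Render an event trace as a grayscale image
#'
#' Renders the deviation-corrected trace as a one-pixel anti-aliased
#' polyline on a fixed 240 x 240 master raster - fixed current axis equal to
#' the clipping band, time spanning the full width, no axes or margins -
#' then area-averages down to the requested resolution. Deviation
#' correction recenters the per-event median to \code{baseLevel} before
#' clipping to the band, so renderings are comparable across events.
#' Intensities encode line coverage: the trace is high-valued (up to 1) on
#' a zero background. The rendering is a deterministic function of
#' (trace, resolution).
#'
#' @param trace an [EventTrace-class] or numeric vector of currents (pA).
#' @param resolution one of 28, 56, 70, 84, 112, 140, 240 (extensible via
#'   \code{allowed}).
#' @param band fixed current axis limits in pA (default c(200, 700)).
#' @param baseLevel recentering target of the deviation correction (pA);
#'   set to NA to skip correction.
#' @param allowed vector of permitted resolutions.
#' @return a [TraceImage-class].
#' @examples
#' img <- renderImage(generateEvent(simConfig(), "delayed", 1), 56)
#' img
#' @export
renderImage <- function(trace, resolution, band = c(200, 700),
                        baseLevel = 450, allowed = .SUPPORTED_RES) {
  resolution <- as.integer(resolution)
  if (!resolution %in% allowed)
    stop("unsupported resolution ", resolution, "; allowed: ",
         paste(allowed, collapse = ", "))
  id <- if (is(trace, "EventTrace")) eventId(trace) else "trace"
  x <- if (is(trace, "EventTrace")) traceSamples(trace) else as.numeric(trace)
  if (length(x) == 0L) stop("empty trace")
  if (!is.na(baseLevel)) x <- x + (baseLevel - median(x))
  x <- pmin(pmax(x, band[1]), band[2])
  master <- .raster_trace_cpp(x, .MASTER_RES, band[1], band[2])
  if (resolution < .MASTER_RES) {
    A <- .resampleMatrix(resolution, .MASTER_RES)
    px <- A %*% master %*% t(A)
  } else px <- master
  px <- pmin(pmax(px, 0), 1)
  new("TraceImage", pixels = px, resolution = resolution, eventId = id)
}

#' Render a list of events
#'
#' @param events list of [EventTrace-class] objects.
#' @param resolution target resolution.
#' @param ... passed to [renderImage()].
#' @return list of [TraceImage-class] objects.
#' @export
renderImages <- function(events, resolution, ...) {
  lapply(events, renderImage, resolution = resolution, ...)
}

# Stack images into a (pixels x n) matrix, column-major per image.
.imageMatrix <- function(images, resolution) {
  stopifnot(length(images) > 0L)
  d <- resolution^2
  X <- matrix(0, d, length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (imageResolution(img) != resolution)
      stop("image resolution ", imageResolution(img),
           " does not match expected ", resolution)
    X[, i] <- as.numeric(imagePixels(img))
  }
  X
}
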