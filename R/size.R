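# Worm-size estimation from cropped grayscale frames and robust smoothing of
# the resulting area series.

#' Estimate a background frame from a video's frames
#'
#' Pixel-wise mean of 8 sample frames at equally spaced indices (first and
#' last frame included).
#'
#' @param frames list of numeric matrices of identical dimensions (>= 8).
#' @return the background matrix.
#' @export
estimateBackground <- function(frames) {
  if (length(frames) < 8L)
    stop("at least 8 frames are required, got ", length(frames))
  idx <- round(seq(1L, length(frames), length.out = 8L))
  picked <- frames[idx]
  Reduce(`+`, picked) / 8
}

#' Normalize a frame against a background estimate
#'
#' Applies \code{(f - b + 100) / 256} element-wise, mapping 8-bit grayscale
#' frames to roughly [0, 1]: background pixels land near 100/256 = 0.39,
#' worm pixels (darker than background) below it.
#'
#' @param frame,background numeric matrices of the same dimensions.
#' @return the normalized frame.
#' @export
normalizeFrame <- function(frame, background) {
  if (!identical(dim(frame), dim(background)))
    stop("frame and background dimensions differ")
  (frame - background + 100) / 256
}

#' Worm area from a normalized frame
#'
#' Thresholds the normalized frame at \code{threshold} (worm pixels are
#' darker, i.e. below it) and requires exactly one closed contour: a single
#' connected dark blob not touching the image border. The area is the number
#' of enclosed pixels, interior holes included. Zero blobs, multiple blobs,
#' or a blob cut by the border yield NA (missing), which is a value, not an
#' error.
#'
#' @param normFrame normalized frame from \code{\link{normalizeFrame}}.
#' @param threshold grayscale threshold (default 0.34).
#' @return integer pixel count, or NA.
#' @export
frameArea <- function(normFrame, threshold = 0.34) {
  mask <- normFrame < threshold
  if (!any(mask)) return(NA_integer_)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  m <- EBImage::imageData(lab)
  if (max(m) != 1L) return(NA_integer_)
  # a blob touching the border has no closed contour
  if (any(m[1L, ] > 0) || any(m[nrow(m), ] > 0) ||
      any(m[, 1L] > 0) || any(m[, ncol(m)] > 0))
    return(NA_integer_)
  filled <- EBImage::imageData(EBImage::fillHull(lab))
  as.integer(sum(filled > 0))
}

#' Running median of an area series
#'
#' Centered running median with an odd window (default 301 frames = 10 min at
#' 3 fps), ignoring missing frames within the window; a window with no valid
#' frames yields NA. Edges use truncated windows.
#'
#' @param areas numeric vector with NAs for missing frames.
#' @param window odd window length in frames.
#' @return smoothed numeric vector of the same length.
#' @export
runningMedian <- function(areas, window = 301L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window == 1L || length(areas) == 0L) return(areas)
  zoo::rollapply(areas, width = window,
                 FUN = function(v) {
                   v <- v[!is.na(v)]
                   if (!length(v)) NA_real_ else median(v)
                 },
                 partial = TRUE, align = "center")
}
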