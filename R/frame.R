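#' Single-channel image frame
#'
#' An `image_frame` is a numeric matrix of pixel intensities with a fixed
#' coordinate convention: `x` is the column index, `y` is the row index,
#' both 0-based, with the origin at the top-left corner.  Pixel `(x, y)` is
#' stored at `pixels[y + 1, x + 1]`.  Raw 8-bit frames hold values in
#' `[0, 255]`; filtered frames may hold any real values.
#'
#' @param pixels numeric matrix (rows = height, columns = width).
#' @param raw logical; if `TRUE`, values are checked against the 8-bit
#'   range `[0, 255]`.
#' @return an `image_frame` (a numeric matrix with class attribute).
#' @examples
#' f <- image_frame(matrix(0, 4, 6))
#' frame_width(f)   # 6
#' frame_height(f)  # 4
#' @export
image_frame <- function(pixels, raw = TRUE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("frame must be at least 1 x 1")
  if (anyNA(pixels))
    stop("frame contains NA pixels")
  if (raw && (min(pixels) < 0 || max(pixels) > 255))
    stop("raw frame values must lie in [0, 255]")
  structure(pixels, class = c("image_frame", class(matrix())))
}

#' @rdname image_frame
#' @param frame an `image_frame` or plain numeric matrix.
#' @export
frame_width <- function(frame) ncol(frame)

#' @rdname image_frame
#' @export
frame_height <- function(frame) nrow(frame)

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame %d x %d px, range [%.4g, %.4g]>\n",
              ncol(x), nrow(x), min(x), max(x)))
  invisible(x)
}

#' Extract the red channel of an RGB image
#'
#' Fluorescence emission captured by the camera contributes predominantly
#' to the red channel, so all downstream analysis runs on that channel
#' alone.  No scaling is applied.
#'
#' @param rgb numeric array `height x width x channels` with at least 3
#'   channels, values in `[0, 255]`.
#' @return an [image_frame] holding the first (red) channel.
#' @export
extract_red_channel <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L)
    stop("expected a 3-dimensional array (height x width x channels)")
  if (dim(rgb)[3] < 3L)
    stop(sprintf(
      "expected an RGB image with >= 3 channels, got %d channel(s)",
      dim(rgb)[3]))
  image_frame(rgb[, , 1L, drop = TRUE], raw = FALSE)
}
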