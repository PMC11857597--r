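#' Read a slide image from a PNG file
#'
#' Reads an 8-bit RGB(A) PNG and returns a `height x width x 3` numeric
#' array on the 0--255 scale.  An alpha channel, if present, is discarded.
#' Grayscale input is rejected: the analysis chain needs the red channel
#' of a colour image.
#'
#' @param path path to a PNG file.
#' @return numeric array `height x width x 3`, values in `[0, 255]`.
#' @seealso [write_png()], [extract_red_channel()]
#' @export
read_png <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read PNG: file not found: %s", path))
  img <- tryCatch(png::readPNG(path),
                  error = function(e)
                    stop(sprintf("cannot decode PNG '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  if (length(dim(img)) != 3L)
    stop(sprintf(
      "expected an RGB image with >= 3 channels, got grayscale input: %s",
      path))
  if (dim(img)[3] < 3L)
    stop(sprintf("expected >= 3 channels, got %d: %s", dim(img)[3], path))
  round(img[, , 1:3, drop = FALSE] * 255)
}

#' Write an RGB image to a PNG file
#'
#' @param image numeric array `height x width x 3`, values in `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(image, path) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("'image' must be a height x width x 3 array")
  if (min(image) < 0 || max(image) > 255)
    stop("image values must lie in [0, 255]")
  png::writePNG(image / 255, target = path)
  invisible(path)
}
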