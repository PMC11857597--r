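#' Spot-detection parameters
#'
#' Tunables of the detection chain: smoothing kernel, threshold rule,
#' and the area/circularity contour gates.
#'
#' @param blur_kernel odd kernel size in pixels (default 9).
#' @param blur_sigma Gaussian sigma in pixels; the default follows the
#'   common kernel-size-derived rule `0.3 * ((k - 1)/2 - 1) + 0.8`.
#' @param threshold_mode one of `"mean_plus_k_sigma"` (default),
#'   `"absolute"`, `"percentile"`.
#' @param threshold_value mode-dependent scalar: the `k` multiplier
#'   (default 3), an absolute intensity, or a percentile in (0, 100).
#' @param min_area minimum contour area in pixels, inclusive (default
#'   100: contours *smaller* than 100 px are discarded).
#' @param min_circularity minimum `4*pi*A/P^2` (default 0.6).
#' @param connectivity pixel connectivity, 4 or 8 (default 8).
#' @param residual_tol maximum RMS residual (px) accepted when fitting
#'   the control-spot grid (default 10).
#' @param min_snr spots with SNR below this are flagged `low_snr`;
#'   the default 0 disables the flag.
#' @return a `detection_params` object.
#' @export
detection_params <- function(blur_kernel = 9L,
                             blur_sigma = NULL,
                             threshold_mode = c("mean_plus_k_sigma",
                                                "absolute", "percentile"),
                             threshold_value = 3,
                             min_area = 100,
                             min_circularity = 0.6,
                             connectivity = 8L,
                             residual_tol = 10,
                             min_snr = 0) {
  blur_kernel <- as.integer(blur_kernel)
  if (blur_kernel < 1L || blur_kernel %% 2L == 0L)
    stop("blur_kernel must be an odd integer >= 1")
  if (is.null(blur_sigma))
    blur_sigma <- 0.3 * ((blur_kernel - 1) / 2 - 1) + 0.8
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "percentile" &&
      (threshold_value <= 0 || threshold_value >= 100))
    stop("percentile threshold_value must lie in (0, 100)")
  if (min_area < 0) stop("min_area must be >= 0")
  if (min_circularity < 0 || min_circularity > 1)
    stop("min_circularity must lie in [0, 1]")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(blur_kernel = blur_kernel, blur_sigma = blur_sigma,
                 threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 min_area = min_area, min_circularity = min_circularity,
                 connectivity = connectivity, residual_tol = residual_tol,
                 min_snr = min_snr),
            class = "detection_params")
}

#' Normalized truncated Gaussian kernels
#'
#' @param size odd kernel size.
#' @param sigma Gaussian sigma in pixels.
#' @return `gaussian_kernel_1d`: numeric vector summing to 1;
#'   `gaussian_kernel`: `size x size` matrix summing to 1.
#' @export
gaussian_kernel_1d <- function(size, sigma) {
  if (size %% 2L == 0L) stop("kernel size must be odd")
  r <- (size - 1) / 2
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' @rdname gaussian_kernel_1d
#' @export
gaussian_kernel <- function(size, sigma) {
  k <- gaussian_kernel_1d(size, sigma)
  outer(k, k)
}

#' Gaussian smoothing
#'
#' Convolves the frame with a normalized truncated 2D Gaussian kernel
#' (9 x 9 by default), separably, with reflective border handling.
#' Output dimensions equal input dimensions.
#'
#' @param frame an [image_frame] or numeric matrix.
#' @param params a [detection_params]; alternatively pass `kernel` /
#'   `sigma` directly.
#' @param kernel,sigma optional overrides of the kernel size and sigma.
#' @return smoothed frame (same dimensions, real-valued).
#' @export
gaussian_blur <- function(frame, params = detection_params(),
                          kernel = params$blur_kernel,
                          sigma = params$blur_sigma) {
  if (kernel %% 2L == 0L) stop("kernel size must be odd")
  if (kernel > nrow(frame) || kernel > ncol(frame))
    stop("kernel does not fit inside the frame")
  k <- gaussian_kernel_1d(kernel, sigma)
  m <- unclass(frame)
  A <- .conv_band_matrix(nrow(m), k)
  B <- .conv_band_matrix(ncol(m), k)
  out <- as.matrix(A %*% m %*% Matrix::t(B))
  image_frame(out, raw = FALSE)
}

# Sparse band matrix implementing 1D convolution with symmetric reflect
# padding (the edge pixel is repeated: pixel 0 maps to 1, -1 to 2 --
# scipy's "reflect" / OpenCV BORDER_REFLECT).  This convention makes the
# operator symmetric and doubly stochastic, so smoothing preserves both
# constants and the total pixel sum.  Reflected taps fold onto in-range
# columns; sparseMatrix sums the duplicates.
.conv_band_matrix <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  i <- rep(seq_len(n), each = length(k))
  j <- i + rep(seq.int(-r, r), times = n)
  j <- ifelse(j < 1L, 1L - j, ifelse(j > n, 2L * n + 1L - j, j))
  Matrix::sparseMatrix(i = i, j = j, x = rep(k, times = n),
                       dims = c(n, n))
}

#' Intensity thresholding
#'
#' Produces a binary mask, `TRUE` where the frame is at or above the
#' resolved threshold.  The threshold is either an absolute intensity,
#' `mean + k * sd` over the whole frame, or a global percentile.
#'
#' @inheritParams gaussian_blur
#' @return logical matrix, same dimensions as `frame`; the resolved
#'   threshold is attached as attribute `"threshold"`.
#' @export
threshold_mask <- function(frame, params = detection_params()) {
  thr <- switch(params$threshold_mode,
    absolute = params$threshold_value,
    mean_plus_k_sigma = mean(frame) + params$threshold_value * stats::sd(frame),
    percentile = stats::quantile(frame, params$threshold_value / 100,
                                 names = FALSE))
  structure(unclass(frame) >= thr, threshold = thr)
}

#' Connected-component labelling
#'
#' Labels the `TRUE` pixels of a mask into connected components under
#' 4- or 8-connectivity by breadth-first frontier expansion.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix: 0 background, 1..n component ids (ids ordered
#'   by the component's first pixel in column-major order).
#' @export
label_components <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  unvisited <- logical(H * W)
  unvisited[fg] <- TRUE
  next_id <- 0L
  for (seed in fg) {
    if (!unvisited[seed]) next
    next_id <- next_id + 1L
    frontier <- seed
    unvisited[seed] <- FALSE
    while (length(frontier)) {
      lab[frontier] <- next_id
      fr <- ((frontier - 1L) %% H) + 1L
      fc <- ((frontier - 1L) %/% H) + 1L
      nb <- integer(0)
      for (d in seq_along(dr)) {
        rr <- fr + dr[d]; cc <- fc + dc[d]
        ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
        if (any(ok)) nb <- c(nb, (cc[ok] - 1L) * H + rr[ok])
      }
      nb <- unique(nb[unvisited[nb]])
      unvisited[nb] <- FALSE
      frontier <- nb
    }
  }
  lab
}

#' Contour extraction from a thresholded mask
#'
#' Reports each connected component of the mask with its area (member
#' pixel count), outer-boundary perimeter, circularity, sub-pixel
#' centroid (unweighted mean of member pixel coordinates, 0-based), and
#' mean raw-frame intensity over the member pixels.
#'
#' Perimeter uses the weighted border-pixel estimator (straight border
#' runs count 1 per pixel, diagonal steps `sqrt(2)`), which is close to
#' unbiased for smooth digital shapes; circularity `4*pi*A/P^2` is
#' clamped to 1, since discretization can push the raw ratio above the
#' continuous-geometry maximum (1-2 px specks have no measurable
#' boundary and report perimeter 0, circularity 1 --- the area gate is
#' what removes them).
#'
#' @param mask logical matrix from [threshold_mask()].
#' @param frame the *raw* frame intensities (same dimensions as `mask`).
#' @param params a [detection_params] (connectivity is used here).
#' @return data.frame with one row per contour: `id`, `x`, `y` (centroid),
#'   `area`, `perimeter`, `circularity`, `mean_intensity`, plus a
#'   `"pixels"` attribute (list of member linear indices).
#' @export
find_contours <- function(mask, frame, params = detection_params()) {
  if (!all(dim(mask) == dim(frame)))
    stop("mask and frame dimensions differ")
  lab <- label_components(mask, params$connectivity)
  n <- max(lab)
  empty <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0), perimeter = numeric(0),
                      circularity = numeric(0), mean_intensity = numeric(0))
  if (n == 0L) return(structure(empty, pixels = list()))
  H <- nrow(mask)
  fg <- which(lab > 0L)
  comp <- lab[fg]
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  area <- tabulate(comp, n)
  cx <- tapply((cols - 1), comp, mean)   # x = col - 1 (0-based)
  cy <- tapply((rows - 1), comp, mean)
  mi <- tapply(unclass(frame)[fg], comp, mean)
  pixels <- split(fg, comp)
  perim <- vapply(seq_len(n), function(i)
    .component_perimeter(lab, i, pixels[[i]]), numeric(1))
  circ <- pmin(1, 4 * pi * area / pmax(perim, 1e-9)^2)
  out <- data.frame(id = seq_len(n), x = as.numeric(cx), y = as.numeric(cy),
                    area = as.numeric(area), perimeter = perim,
                    circularity = circ, mean_intensity = as.numeric(mi))
  structure(out, pixels = pixels)
}

# Weighted border-pixel perimeter (the standard digital-perimeter
# estimator: border pixels are categorized by their border-pixel
# neighbourhood and weighted 1, sqrt(2) or (1+sqrt(2))/2, which is
# unbiased for smooth shapes).  Components of 1-2 pixels have no
# interior/border structure; they get a nominal crack perimeter.
.component_perimeter <- function(lab, id, pix) {
  H <- nrow(lab)
  rows <- ((pix - 1L) %% H) + 1L
  cols <- ((pix - 1L) %/% H) + 1L
  h <- max(rows) - min(rows) + 3L
  w <- max(cols) - min(cols) + 3L
  m <- matrix(FALSE, h, w)
  m[cbind(rows - min(rows) + 2L, cols - min(cols) + 2L)] <- TRUE
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, h, w)
    rs <- max(1L, 1L + dr):min(h, h + dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  interior <- m & shift(m, 1L, 0L) & shift(m, -1L, 0L) &
    shift(m, 0L, 1L) & shift(m, 0L, -1L)
  border <- m & !interior
  if (!any(border)) return(0)
  b <- border * 1
  code <- b +
    2 * (shift(border, 1L, 0L) + shift(border, -1L, 0L) +
         shift(border, 0L, 1L) + shift(border, 0L, -1L)) +
    10 * (shift(border, 1L, 1L) + shift(border, 1L, -1L) +
          shift(border, -1L, 1L) + shift(border, -1L, -1L))
  wts <- numeric(50)
  wts[c(5, 7, 15, 17, 25, 27)] <- 1
  wts[c(21, 33)] <- sqrt(2)
  wts[c(13, 23)] <- (1 + sqrt(2)) / 2
  cd <- code[border]
  sum(wts[cd[cd >= 1 & cd <= 50]])
}

#' Area and circularity gate
#'
#' Retains contours with `area >= min_area` and
#' `circularity >= min_circularity`, preserving input order.  Dust and
#' other non-specific debris fall below the area cut (the instrument's
#' experimentally determined minimum spot size); elongated smears fail
#' the circularity cut.
#'
#' @param contours data.frame from [find_contours()].
#' @param params a [detection_params].
#' @return filtered data.frame (member-pixel attribute subset to match).
#' @export
filter_contours <- function(contours, params = detection_params()) {
  keep <- contours$area >= params$min_area &
    contours$circularity >= params$min_circularity
  out <- contours[keep, , drop = FALSE]
  px <- attr(contours, "pixels")
  if (!is.null(px)) attr(out, "pixels") <- px[keep]
  out
}
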