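#' Segment a frame into horizontal row bands
#'
#' Partitions the frame height into `n_rows` contiguous, non-overlapping
#' bands of near-equal height; remainder pixels go to the last band.
#' When row centres are supplied (e.g. from a fitted grid), bands are
#' instead centred on them, with boundaries at the midpoints between
#' consecutive centres.
#'
#' @param frame an [image_frame] or numeric matrix.
#' @param n_rows number of bands.
#' @param centers optional numeric vector of row-centre y coordinates
#'   (0-based), length `n_rows`.
#' @return data.frame: `row_index` (1-based), `y0`, `y1` --- each band is
#'   the half-open pixel interval `[y0, y1)` in 0-based y coordinates.
#' @export
segment_rows <- function(frame, n_rows, centers = NULL) {
  H <- nrow(frame)
  n_rows <- as.integer(n_rows)
  if (n_rows < 1L) stop("n_rows must be >= 1")
  if (n_rows > H) stop("n_rows exceeds frame height")
  if (is.null(centers)) {
    h <- H %/% n_rows
    y0 <- (seq_len(n_rows) - 1L) * h
    y1 <- c(y0[-1L], H)
  } else {
    stopifnot(length(centers) == n_rows)
    mids <- (centers[-1L] + centers[-n_rows]) / 2
    y0 <- floor(c(0, mids))
    y1 <- c(y0[-1L], H)
  }
  data.frame(row_index = seq_len(n_rows), y0 = y0, y1 = y1)
}

#' Background-subtracted row intensity profile
#'
#' The profile value at column x is the column statistic (mean by
#' default) over the band's rows, minus the band's background estimate
#' (the median of all band pixels).  Values may be negative after
#' subtraction.
#'
#' @param frame an [image_frame] or numeric matrix.
#' @param band one-row band (fields `y0`, `y1`, `row_index`) from
#'   [segment_rows()].
#' @param stat `"mean"` (default) or `"max"` column statistic.
#' @return an `intensity_profile`: list with `positions` (0-based x),
#'   `values`, `row_index`.
#' @export
row_profile <- function(frame, band, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  H <- nrow(frame)
  if (band$y1 <= band$y0 || band$y0 < 0 || band$y1 > H)
    stop("band lies outside the frame or is empty")
  rows <- (band$y0 + 1L):band$y1
  m <- unclass(frame)[rows, , drop = FALSE]
  vals <- if (stat == "mean") colMeans(m) else apply(m, 2, max)
  structure(list(positions = seq_len(ncol(frame)) - 1L,
                 values = unname(vals - stats::median(m)),
                 row_index = band$row_index),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile row %d: %d positions, max %.2f>\n",
              x$row_index, length(x$positions), max(x$values)))
  invisible(x)
}

#' @export
plot.intensity_profile <- function(x, ...) {
  graphics::plot(x$positions, x$values, type = "l",
                 xlab = "x (px)", ylab = "net intensity",
                 main = sprintf("Row %d intensity profile", x$row_index),
                 ...)
  invisible(x)
}

#' Peak detection on an intensity profile
#'
#' Local maxima of the profile at or above `min_height`, accepted
#' greedily in descending height order with non-maximum suppression:
#' a candidate within `min_separation` px of an already accepted peak is
#' discarded.  Ties are broken towards smaller x.  Plateau maxima are
#' reported at their leftmost position.
#'
#' @param profile an `intensity_profile` from [row_profile()].
#' @param min_height minimum peak value.
#' @param min_separation minimum distance between accepted peaks (px,
#'   >= 1).
#' @return data.frame `position`, `height`, sorted by position.
#' @export
detect_peaks <- function(profile, min_height, min_separation = 1) {
  if (min_separation < 1) stop("min_separation must be >= 1")
  v <- profile$values
  n <- length(v)
  if (n < 3L) return(data.frame(position = numeric(0), height = numeric(0)))
  # compress equal-value runs; a run is a local maximum when it exceeds
  # both neighbouring runs and does not touch the profile edge (so flat
  # profiles and half-plateaus at the borders yield nothing); plateau
  # maxima are reported at their leftmost position
  r <- rle(v)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(data.frame(position = numeric(0), height = numeric(0)))
  prev <- c(-Inf, r$values[-k])
  nxt <- c(r$values[-1L], -Inf)
  is_max <- r$values > prev & r$values > nxt &
    run_start > 1L & run_end < n & r$values >= min_height
  cand <- run_start[is_max]
  if (!length(cand)) return(data.frame(position = numeric(0),
                                       height = numeric(0)))
  ord <- cand[order(-v[cand], cand)]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= min_separation))
      accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  data.frame(position = profile$positions[accepted],
             height = v[accepted])
}

#' Render per-row QC profile plots to a PNG file
#'
#' One panel per band, mirroring the instrument's row-profile QC view.
#'
#' @param frame an [image_frame] or numeric matrix.
#' @param n_rows number of bands.
#' @param path output PNG path.
#' @param stat column statistic passed to [row_profile()].
#' @export
plot_row_profiles <- function(frame, n_rows, path, stat = "mean") {
  bands <- segment_rows(frame, n_rows)
  grDevices::png(path, width = 900, height = 220 * n_rows)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(n_rows, 1), mar = c(3, 4, 2, 1))
  for (i in seq_len(n_rows))
    plot(row_profile(frame, bands[i, ], stat = stat))
  invisible(path)
}
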