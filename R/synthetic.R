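#' Synthetic slide scene configuration
#'
#' Describes one rendered well: the printed layout, per-spot peak
#' amplitudes, an additive background plane, Gaussian pixel noise, the
#' spot point-spread width, and optional dust artifacts.  The rendered
#' frame is a desk-scale stand-in for the native sensor raster: layout
#' coordinates are rescaled from the layout's reference size to
#' `width` x `height`.
#'
#' @param layout an [array_layout].
#' @param amplitudes named numeric vector, spot label -> peak amplitude
#'   (0--255 intensity units, added to the background in the red channel).
#' @param background_level constant background intensity (default 20).
#' @param background_gradient length-2 slope `c(gx, gy)` in intensity per
#'   pixel (default `c(0, 0)`).
#' @param noise_sigma standard deviation of additive Gaussian pixel noise
#'   (default 5).
#' @param spot_sigma isotropic Gaussian spot width in rendered pixels
#'   (default 6).
#' @param artifacts data.frame with columns `x`, `y`, `radius`,
#'   `amplitude`: hard discs emulating dust (default: none).
#' @param seed integer; fully determines the rendered image.
#' @param width,height rendered frame size (default 1024 x 768).
#' @param allow_saturation if `FALSE` (default), a configuration whose
#'   background plus peak amplitude exceeds 255 is rejected rather than
#'   silently clipped.
#' @return a `scene_config` object.
#' @seealso [render_synthetic_array()], [default_amplitudes()]
#' @export
scene_config <- function(layout = default_layout(),
                         amplitudes = default_amplitudes(layout),
                         background_level = 20,
                         background_gradient = c(0, 0),
                         noise_sigma = 5,
                         spot_sigma = 6,
                         artifacts = NULL,
                         seed = 1L,
                         width = 1024L, height = 768L,
                         allow_saturation = FALSE) {
  stopifnot(inherits(layout, "array_layout"))
  missing_amp <- setdiff(layout$spots$label, names(amplitudes))
  if (length(missing_amp))
    stop("amplitudes missing for labels: ",
         paste(missing_amp, collapse = ", "))
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  top <- background_level +
    max(0, background_gradient[1] * (width - 1)) +
    max(0, background_gradient[2] * (height - 1)) +
    max(amplitudes, if (!is.null(artifacts)) artifacts$amplitude else 0)
  if (!allow_saturation && top > 255)
    stop(sprintf(
      "peak amplitude + background = %.1f exceeds 255; set allow_saturation = TRUE to render a deliberately clipped scene",
      top))
  if (!is.null(artifacts)) {
    stopifnot(all(c("x", "y", "radius", "amplitude") %in% names(artifacts)))
  }
  structure(
    list(layout = layout, amplitudes = amplitudes,
         background_level = background_level,
         background_gradient = background_gradient,
         noise_sigma = noise_sigma, spot_sigma = spot_sigma,
         artifacts = artifacts, seed = as.integer(seed),
         width = as.integer(width), height = as.integer(height),
         allow_saturation = allow_saturation),
    class = "scene_config")
}

#' Default per-spot amplitudes
#'
#' Two stated worlds are provided.  `"qc"` emulates a quality-control
#' slide on which every printed spot fluoresces (positive controls at
#' 180, negative-control positions at 150, and a five-step test-spot
#' ladder 80/110/140/170/200 across the analytes, identical across
#' replicates).  `"assay"` emulates a sample assay: PBS negative
#' controls carry no dye (amplitude 0) and test amplitudes are the
#' ladder unless overridden.
#'
#' @param layout an [array_layout].
#' @param mode `"qc"` or `"assay"`.
#' @param test_amplitudes optional named vector, analyte -> amplitude,
#'   overriding the ladder.
#' @return named numeric vector over all layout labels.
#' @export
default_amplitudes <- function(layout = default_layout(),
                               mode = c("qc", "assay"),
                               test_amplitudes = NULL) {
  mode <- match.arg(mode)
  sp <- layout$spots
  ladder <- seq(80, 200, length.out =
                  length(unique(stats::na.omit(sp$analyte))))
  names(ladder) <- unique(stats::na.omit(sp$analyte))
  if (!is.null(test_amplitudes)) ladder[names(test_amplitudes)] <- test_amplitudes
  amp <- numeric(nrow(sp))
  amp[sp$role == "control_positive"] <- 180
  amp[sp$role == "control_negative"] <- if (mode == "qc") 150 else 0
  amp[sp$role == "test"] <- ladder[sp$analyte[sp$role == "test"]]
  names(amp) <- sp$label
  amp
}

#' Render a synthetic microarray well
#'
#' Each spot is rendered as an isotropic Gaussian profile of the
#' configured peak amplitude and width, centred on its (rescaled) layout
#' position; dust artifacts are hard discs.  All signal is placed in the
#' red channel on top of the background plane; Gaussian noise is added,
#' the result is quantized with round-half-up and clipped to `[0, 255]`.
#' The green and blue channels carry a dim constant (20% of the
#' background level) so the image looks like a camera frame but carries
#' no analysable signal there.
#'
#' The returned ground truth records, per spot, the exact rendered
#' centre, the true peak amplitude, and the true mean of the spot's own
#' (noise-free, pre-quantization) contribution over its footprint --- the
#' disc of radius `2 * spot_sigma` --- which is the reference value for
#' net-intensity recovery checks.
#'
#' @param config a [scene_config].
#' @return list with elements `image` (`height x width x 3` array,
#'   0--255), `truth` (data.frame: `label`, `role`, `analyte`,
#'   `replicate`, `x`, `y`, `true_peak`, `true_mean`, `saturated`) and
#'   `artifacts` (the rendered artifact table, possibly `NULL`).
#' @export
render_synthetic_array <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  W <- config$width; H <- config$height
  lay <- config$layout
  sx <- W / lay$ref_width; sy <- H / lay$ref_height
  sp <- lay$spots
  cx <- sp$x * sx; cy <- sp$y * sy
  amp <- config$amplitudes[sp$label]
  sig <- config$spot_sigma

  # background plane (x = col-1, y = row-1, 0-based)
  gx <- config$background_gradient[1]; gy <- config$background_gradient[2]
  red <- matrix(config$background_level, H, W)
  if (gx != 0) red <- red + matrix(gx * (seq_len(W) - 1), H, W, byrow = TRUE)
  if (gy != 0) red <- red + matrix(gy * (seq_len(H) - 1), H, W)

  truth_mean <- numeric(nrow(sp))
  half <- ceiling(4 * sig)
  for (i in seq_len(nrow(sp))) {
    if (amp[i] <= 0) next
    res <- .add_gaussian_spot(red, cx[i], cy[i], amp[i], sig, half)
    red <- res$frame
    truth_mean[i] <- res$footprint_mean
  }
  if (!is.null(config$artifacts)) {
    af <- config$artifacts
    for (i in seq_len(nrow(af))) {
      cols <- pmax(1L, floor(af$x[i] - af$radius[i]) + 1L):
        pmin(W, ceiling(af$x[i] + af$radius[i]) + 1L)
      rows <- pmax(1L, floor(af$y[i] - af$radius[i]) + 1L):
        pmin(H, ceiling(af$y[i] + af$radius[i]) + 1L)
      dx <- (cols - 1) - af$x[i]; dy <- (rows - 1) - af$y[i]
      d2 <- outer(dy^2, dx^2, `+`)
      patch <- red[rows, cols, drop = FALSE]
      patch[d2 <= af$radius[i]^2] <- patch[d2 <= af$radius[i]^2] + af$amplitude[i]
      red[rows, cols] <- patch
    }
  }

  if (config$noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(config$seed)
    red <- red + matrix(stats::rnorm(H * W, 0, config$noise_sigma), H, W)
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
    else
      rm(".Random.seed", envir = globalenv())
  }

  saturated_px <- red > 255
  red_q <- pmin(255, pmax(0, floor(red + 0.5)))

  side <- matrix(round(0.2 * config$background_level), H, W)
  image <- array(0, dim = c(H, W, 3L))
  image[, , 1] <- red_q
  image[, , 2] <- side
  image[, , 3] <- side

  sat_flag <- logical(nrow(sp))
  if (any(saturated_px)) {
    for (i in seq_len(nrow(sp))) {
      rows <- pmax(1L, round(cy[i]) - half):pmin(H, round(cy[i]) + half)
      cols <- pmax(1L, round(cx[i]) - half):pmin(W, round(cx[i]) + half)
      sat_flag[i] <- any(saturated_px[rows, cols])
    }
  }

  truth <- data.frame(
    label = sp$label, role = sp$role, analyte = sp$analyte,
    replicate = sp$replicate, x = cx, y = cy,
    true_peak = unname(amp), true_mean = truth_mean,
    saturated = sat_flag)
  list(image = image, truth = truth, artifacts = config$artifacts)
}

# Adds one Gaussian spot to `frame` in place (window of +-`half` px) and
# returns the mean of the spot's own contribution over the footprint disc
# of radius 2*sigma, evaluated on the pixel grid.
.add_gaussian_spot <- function(frame, cx, cy, amp, sigma, half) {
  H <- nrow(frame); W <- ncol(frame)
  cols <- pmax(1L, floor(cx) - half + 1L):pmin(W, ceiling(cx) + half + 1L)
  rows <- pmax(1L, floor(cy) - half + 1L):pmin(H, ceiling(cy) + half + 1L)
  dx <- (cols - 1) - cx; dy <- (rows - 1) - cy
  d2 <- outer(dy^2, dx^2, `+`)
  g <- amp * exp(-d2 / (2 * sigma^2))
  frame[rows, cols] <- frame[rows, cols] + g
  fp <- d2 <= (2 * sigma)^2
  list(frame = frame, footprint_mean = mean(g[fp]))
}

#' Write renderer ground truth to CSV
#'
#' @param truth the `truth` element of [render_synthetic_array()].
#' @param path output file path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
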