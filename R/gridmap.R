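#' Anchor detected contours to the printed layout
#'
#' Assigns detected contours to the layout's *positive* control spots
#' (negative controls carry no dye and cannot be detected from the
#' image) by optimal one-to-one assignment on centroid-to-expected
#' distance, then fits a similarity transform (translation + isotropic
#' scale, optionally rotation) from layout space to image space by least
#' squares on the assigned pairs.
#'
#' Layout coordinates are first rescaled from the layout's reference
#' raster to the analysed frame size; the fitted transform absorbs the
#' residual seating shift and scale of the slide.
#'
#' @param contours filtered contour table from [filter_contours()].
#' @param layout an [array_layout].
#' @param frame_dim `c(height, width)` of the analysed frame.
#' @param params a [detection_params] (`residual_tol` is used here).
#' @param rotation if `TRUE`, fit a full 2D similarity including
#'   rotation; default `FALSE` (slide seating is dominated by shift and
#'   scale).
#' @return a `grid_map`: list with `assignments` (data.frame label,
#'   contour id, x, y), `scale`, `rotation`, `translation`, `pre_scale`
#'   (reference-to-frame axis scaling), `residual` (RMS px) and
#'   `frame_dim`.
#' @export
identify_controls <- function(contours, layout, frame_dim,
                              params = detection_params(),
                              rotation = FALSE) {
  stopifnot(inherits(layout, "array_layout"))
  sp <- layout$spots
  ctrl <- sp[sp$role == "control_positive", , drop = FALSE]
  n_need <- nrow(ctrl)
  if (nrow(contours) < n_need)
    stop(sprintf(
      "control-spot detection failure: %d contour(s) available for %d positive controls",
      nrow(contours), n_need))
  sx <- frame_dim[2] / layout$ref_width
  sy <- frame_dim[1] / layout$ref_height
  exp_xy <- cbind(ctrl$x * sx, ctrl$y * sy)
  det_xy <- cbind(contours$x, contours$y)
  cost <- outer(seq_len(n_need), seq_len(nrow(contours)),
                function(i, j) sqrt((exp_xy[i, 1] - det_xy[j, 1])^2 +
                                    (exp_xy[i, 2] - det_xy[j, 2])^2))
  sol <- clue::solve_LSAP(cost)
  j <- as.integer(sol)
  fit <- .fit_similarity(exp_xy, det_xy[j, , drop = FALSE], rotation)
  if (!is.finite(fit$residual) || fit$residual > params$residual_tol)
    stop(sprintf(
      "grid alignment failure: control fit residual %.2f px exceeds tolerance %.2f px",
      fit$residual, params$residual_tol))
  structure(
    list(assignments = data.frame(label = ctrl$label,
                                  contour_id = contours$id[j],
                                  x = det_xy[j, 1], y = det_xy[j, 2]),
         scale = fit$scale, rotation = fit$theta,
         translation = fit$translation,
         pre_scale = c(sx, sy), residual = fit$residual,
         frame_dim = frame_dim),
    class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf(
    "<grid_map: %d controls assigned, scale %.4f, shift (%.1f, %.1f), residual %.3f px>\n",
    nrow(x$assignments), x$scale, x$translation[1], x$translation[2],
    x$residual))
  invisible(x)
}

# Least-squares similarity fit q ~ s R p + t.  Without rotation this is
# the scalar regression of centred coordinates; with rotation it is the
# 2D Procrustes/Kabsch solution.
.fit_similarity <- function(p, q, rotation = FALSE) {
  pm <- colMeans(p); qm <- colMeans(q)
  pc <- sweep(p, 2, pm); qc <- sweep(q, 2, qm)
  if (rotation) {
    M <- crossprod(qc, pc)   # sum q p^T
    a <- M[1, 1] + M[2, 2]
    b <- M[2, 1] - M[1, 2]
    theta <- atan2(b, a)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    s <- (a * cos(theta) + b * sin(theta)) / sum(pc^2)
  } else {
    theta <- 0
    R <- diag(2)
    s <- sum(pc * qc) / sum(pc^2)
  }
  t_vec <- qm - s * as.vector(R %*% pm)
  pred <- t(s * R %*% t(p)) + matrix(t_vec, nrow(p), 2, byrow = TRUE)
  list(scale = s, theta = theta, translation = t_vec,
       residual = sqrt(mean(rowSums((q - pred)^2))))
}

#' Map layout coordinates into the image
#'
#' @param grid a `grid_map` from [identify_controls()].
#' @param xy matrix of layout-space coordinates (columns x, y).
#' @return matrix of image-space coordinates.
#' @export
transform_layout_xy <- function(grid, xy) {
  xy <- rbind(xy)
  p <- cbind(xy[, 1] * grid$pre_scale[1], xy[, 2] * grid$pre_scale[2])
  R <- matrix(c(cos(grid$rotation), sin(grid$rotation),
                -sin(grid$rotation), cos(grid$rotation)), 2, 2)
  t(grid$scale * R %*% t(p)) +
    matrix(grid$translation, nrow(p), 2, byrow = TRUE)
}

#' Locate test-spot regions of interest
#'
#' Maps every test spot's expected position through the fitted grid
#' transform and applies the bounded-search rule: a position is
#' admissible only if it lies within the (scaled) `search_range` of the
#' anchor-row axis on either side *and* inside the rectangle spanned by
#' the mapped bound controls (C4 and C7 by default, inclusive).
#' Positions outside the admissible region are flagged missing and get
#' no ROI.
#'
#' @param grid a `grid_map`.
#' @param layout an [array_layout].
#' @return data.frame: `label`, `x`, `y` (ROI centre), `half` (ROI
#'   half-side, px; side is `2 * radius * scale`, at least 9), `missing`.
#' @export
locate_test_spots <- function(grid, layout) {
  sp <- layout$spots
  tests <- sp[sp$role == "test", , drop = FALSE]
  anchors <- grid$assignments[match(layout$anchor_labels,
                                    grid$assignments$label), ]
  bounds <- grid$assignments[match(layout$bound_labels,
                                   grid$assignments$label), ]
  if (anyNA(bounds$x) || anyNA(anchors$x))
    stop("configuration error: anchor or bound labels absent from the grid map")
  mapped <- transform_layout_xy(grid, cbind(tests$x, tests$y))
  s_total <- grid$scale * mean(grid$pre_scale)
  range_px <- layout$search_range * s_total
  # anchor-row axis: line through first and last anchor centroids
  a1 <- c(anchors$x[1], anchors$y[1])
  a2 <- c(anchors$x[nrow(anchors)], anchors$y[nrow(anchors)])
  v <- a2 - a1
  v <- v / sqrt(sum(v^2))
  n_vec <- c(-v[2], v[1])
  d_axis <- abs((mapped[, 1] - a1[1]) * n_vec[1] +
                (mapped[, 2] - a1[2]) * n_vec[2])
  xr <- range(bounds$x); yr <- range(bounds$y)
  # sub-pixel slack: detected bound centroids jitter by fractions of a
  # pixel, and the outer spot rows sit exactly on the bound rows; a spot
  # a full pixel beyond the bounds is still rejected
  eps <- 0.5
  inside <- d_axis <= range_px + eps &
    mapped[, 1] >= xr[1] - eps & mapped[, 1] <= xr[2] + eps &
    mapped[, 2] >= yr[1] - eps & mapped[, 2] <= yr[2] + eps
  half <- pmax(4L, as.integer(round(tests$radius * s_total)))
  data.frame(label = tests$label, x = mapped[, 1], y = mapped[, 2],
             half = half, missing = !inside)
}

#' Quantify one spot
#'
#' Measures the mean raw intensity over the measurement aperture --- the
#' disc inscribed in the ROI, centred on the detected contour centroid
#' when a filtered contour falls inside the ROI, else on the mapped ROI
#' centre --- and subtracts the local background, estimated as the
#' median of a square annulus around the ROI (inner margin 2 px, outer
#' margin 8 px), excluding pixels belonging to any other ROI.  SNR is
#' the net intensity divided by the annulus standard deviation.
#'
#' @param frame raw [image_frame].
#' @param roi one-row ROI (fields `x`, `y`, `half` as produced by
#'   [locate_test_spots()]), or a list with those fields.
#' @param params a [detection_params].
#' @param contours optional filtered contour table used to re-centre the
#'   aperture.
#' @param other_rois optional data.frame of the remaining ROIs whose
#'   pixels are excluded from the background annulus.
#' @return one-row data.frame: `x`, `y`, `mean`, `background`, `net`,
#'   `snr`, `area`, `saturated`, `low_snr`, `clipped`.
#' @export
quantify_spot <- function(frame, roi, params = detection_params(),
                          contours = NULL, other_rois = NULL) {
  H <- nrow(frame); W <- ncol(frame)
  cx <- roi$x; cy <- roi$y; half <- roi$half
  if (cx + half < 0 || cx - half > W - 1 || cy + half < 0 || cy - half > H - 1)
    stop("ROI lies fully outside the frame")
  # re-centre on a detected contour centroid inside the ROI, if any
  if (!is.null(contours) && nrow(contours)) {
    inroi <- abs(contours$x - cx) <= half & abs(contours$y - cy) <= half
    if (any(inroi)) {
      k <- which(inroi)[which.min((contours$x[inroi] - cx)^2 +
                                  (contours$y[inroi] - cy)^2)]
      cx <- contours$x[k]; cy <- contours$y[k]
    }
  }
  clipped <- cx - half < 0 || cx + half > W - 1 ||
    cy - half < 0 || cy + half > H - 1
  cols <- max(1L, ceiling(cx - half) + 1L):min(W, floor(cx + half) + 1L)
  rows <- max(1L, ceiling(cy - half) + 1L):min(H, floor(cy + half) + 1L)
  dx <- (cols - 1) - cx; dy <- (rows - 1) - cy
  d2 <- outer(dy^2, dx^2, `+`)
  disc <- d2 <= half^2
  patch <- unclass(frame)[rows, cols, drop = FALSE]
  mean_int <- mean(patch[disc])
  area <- sum(disc)

  ann <- .annulus_values(frame, cx, cy, half, inner = 2L, outer = 8L,
                         exclude = other_rois)
  bg <- if (length(ann)) stats::median(ann) else 0
  bg_sd <- if (length(ann) > 1) stats::sd(ann) else 0
  net <- mean_int - bg
  snr <- if (bg_sd > 0) net / bg_sd else if (net == 0) 0 else Inf
  data.frame(x = cx, y = cy, mean = mean_int, background = bg, net = net,
             snr = snr, area = area,
             saturated = any(patch[disc] >= 255),
             low_snr = is.finite(snr) && snr < params$min_snr &&
               params$min_snr > 0,
             clipped = clipped)
}

.annulus_values <- function(frame, cx, cy, half, inner, outer,
                            exclude = NULL) {
  H <- nrow(frame); W <- ncol(frame)
  r_out <- half + outer
  cols <- max(1L, ceiling(cx - r_out) + 1L):min(W, floor(cx + r_out) + 1L)
  rows <- max(1L, ceiling(cy - r_out) + 1L):min(H, floor(cy + r_out) + 1L)
  xg <- matrix((cols - 1), length(rows), length(cols), byrow = TRUE)
  yg <- matrix((rows - 1), length(rows), length(cols))
  cheb <- pmax(abs(xg - cx), abs(yg - cy))
  keep <- cheb > half + inner & cheb <= r_out
  if (!is.null(exclude) && nrow(exclude)) {
    for (i in seq_len(nrow(exclude))) {
      keep <- keep & !(abs(xg - exclude$x[i]) <= exclude$half[i] &
                       abs(yg - exclude$y[i]) <= exclude$half[i])
    }
  }
  unclass(frame)[rows, cols, drop = FALSE][keep]
}

#' Process one well image end to end
#'
#' Composes the full detection chain: red-channel extraction, Gaussian
#' smoothing, intensity thresholding, contour labelling, area and
#' circularity filtering, control-spot grid anchoring, bounded test-spot
#' localization, and per-spot quantification.  Controls and test-spot
#' triplicates are returned un-aggregated.
#'
#' @param image `height x width x 3` array (0--255) or a file path to a
#'   PNG.
#' @param layout an [array_layout].
#' @param params a [detection_params].
#' @param well_id optional identifier copied into the output.
#' @return data.frame with one row per layout spot: `well_id`, `label`,
#'   `role`, `analyte`, `replicate`, `x`, `y`, `mean`, `background`,
#'   `net`, `snr`, `area`, `saturated`, `low_snr`, `missing`.
#' @export
process_well <- function(image, layout = default_layout(),
                         params = detection_params(), well_id = NA) {
  if (is.character(image)) image <- read_png(image)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  raw <- stage("extract_red_channel", extract_red_channel(image))
  blurred <- stage("gaussian_blur", gaussian_blur(raw, params))
  mask <- stage("threshold_mask", threshold_mask(blurred, params))
  contours <- stage("find_contours", find_contours(mask, raw, params))
  contours <- stage("filter_contours", filter_contours(contours, params))
  grid <- stage("identify_controls",
                identify_controls(contours, layout, dim(raw), params))
  rois_test <- stage("locate_test_spots", locate_test_spots(grid, layout))

  sp <- layout$spots
  s_total <- grid$scale * mean(grid$pre_scale)
  rois <- data.frame(label = sp$label, x = NA_real_, y = NA_real_,
                     half = pmax(4L, as.integer(round(sp$radius * s_total))),
                     missing = FALSE)
  # positive controls: centre on their assigned contours
  m <- match(grid$assignments$label, rois$label)
  rois$x[m] <- grid$assignments$x
  rois$y[m] <- grid$assignments$y
  # negative controls: mapped through the transform
  negs <- sp$role == "control_negative"
  if (any(negs)) {
    mapped <- transform_layout_xy(grid, cbind(sp$x[negs], sp$y[negs]))
    rois$x[negs] <- mapped[, 1]; rois$y[negs] <- mapped[, 2]
  }
  # test spots: bounded-search localization
  mt <- match(rois_test$label, rois$label)
  rois$x[mt] <- rois_test$x
  rois$y[mt] <- rois_test$y
  rois$half[mt] <- rois_test$half
  rois$missing[mt] <- rois_test$missing

  out <- vector("list", nrow(rois))
  for (i in seq_len(nrow(rois))) {
    if (rois$missing[i] || is.na(rois$x[i])) {
      out[[i]] <- data.frame(x = NA_real_, y = NA_real_, mean = NA_real_,
                             background = NA_real_, net = NA_real_,
                             snr = NA_real_, area = NA_real_,
                             saturated = FALSE, low_snr = FALSE,
                             clipped = FALSE)
      next
    }
    out[[i]] <- stage("quantify_spot",
                      quantify_spot(raw, rois[i, ], params,
                                    contours = contours,
                                    other_rois = rois[-i, ][!rois$missing[-i] &
                                                            !is.na(rois$x[-i]), ]))
  }
  q <- do.call(rbind, out)
  data.frame(well_id = well_id, label = sp$label, role = sp$role,
             analyte = sp$analyte, replicate = sp$replicate,
             x = q$x, y = q$y, mean = q$mean, background = q$background,
             net = q$net, snr = q$snr, area = q$area,
             saturated = q$saturated, low_snr = q$low_snr,
             missing = rois$missing)
}

#' Write spot measurements to CSV
#'
#' Column layout is fixed: `well_id`, `label`, `role`, `analyte`,
#' `replicate`, `x`, `y`, `mean`, `background`, `net`, `snr`, `area`,
#' `saturated`, `low_snr`, `missing`.
#'
#' @param measurements output of [process_well()] (rows from several
#'   wells may be concatenated).
#' @param path output file path.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}
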