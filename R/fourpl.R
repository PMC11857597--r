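#' Fit a four-parameter logistic standard curve
#'
#' Fits the 4PL model
#' \deqn{y(x) = d + \frac{a - d}{1 + (x/c)^b}}
#' to a concentration series by least squares, where `a` is the response
#' at zero concentration, `d` the response at infinite concentration,
#' `c` the inflection concentration (EC50) and `b` the slope factor.
#' The fit is deterministic: fixed self-starting values (`a = min(y)`,
#' `d = max(y)`, `c =` geometric mean of the nonzero concentrations,
#' `b = 1`), Gauss-Newton with a bounded `c > 0` (`nls`, port
#' algorithm), and a Nelder-Mead fallback on the same objective if that
#' fails.  No randomness is involved.
#'
#' A constant-response series cannot identify the curve; it is returned
#' as a degenerate flat fit (`a = d =` mean response) with
#' `r.squared = 1` by the `SS_tot = 0` convention, flagged via
#' `$degenerate`.
#'
#' @param concentration numeric vector of standard concentrations
#'   (>= 0; at least 4 distinct values).
#' @param intensity numeric vector of measured responses, same length.
#' @param weights `"none"` (default) or `"inv_y2"` for `1/y^2`
#'   weighting.
#' @return an object of class `fourpl` with components `coefficients`
#'   (a, b, c, d), `r.squared`, `fitted.values`, `residuals`, `data`,
#'   `degenerate`, `method`.
#' @examples
#' x <- rep(5 * 3^(-3:3), each = 3)
#' y <- 60000 + (10 - 60000) / (1 + (x / 5)^1.2)
#' fit <- fit_4pl(x, y)
#' coef(fit)
#' predict(fit, newdata = c(1, 5, 25))
#' @seealso [invert_4pl()], [predict.fourpl()]
#' @export
fit_4pl <- function(concentration, intensity, weights = c("none", "inv_y2")) {
  weights <- match.arg(weights)
  x <- as.numeric(concentration); y <- as.numeric(intensity)
  if (length(x) != length(y)) stop("concentration/intensity length mismatch")
  if (any(!is.finite(y)) || any(!is.finite(x)) || any(x < 0))
    stop("concentrations must be finite and >= 0; intensities finite")
  if (length(unique(x)) < 4L)
    stop("need at least 4 distinct concentrations to fit a 4PL curve")
  w <- if (weights == "inv_y2") 1 / pmax(y^2, .Machine$double.eps) else
    rep(1, length(y))

  ybar <- stats::weighted.mean(y, w)
  ss_tot <- sum(w * (y - ybar)^2)
  if (ss_tot == 0) {
    cf <- c(a = ybar, b = 1,
            c = exp(mean(log(x[x > 0]))), d = ybar)
    return(structure(list(coefficients = cf, r.squared = 1,
                          fitted.values = rep(ybar, length(y)),
                          residuals = y - ybar,
                          data = data.frame(concentration = x, intensity = y),
                          degenerate = TRUE, method = "degenerate"),
                     class = "fourpl"))
  }

  # orientation-aware start: a from the low-concentration end, d from
  # the high end, so increasing and decreasing curves both start near
  # the right branch; b = 1, c = geometric mean of nonzero standards
  start <- list(a = mean(y[x == min(x)]), d = mean(y[x == max(x)]),
                c = exp(mean(log(x[x > 0]))), b = 1)
  fit <- tryCatch(
    stats::nls(y ~ d + (a - d) / (1 + (x / c)^b), start = start,
               weights = w, algorithm = "port",
               lower = c(a = -Inf, d = -Inf, c = .Machine$double.eps,
                         b = -Inf),
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)[c("a", "b", "c", "d")]
    method <- "nls-port"
  } else {
    obj <- function(p) {
      cc <- exp(p[3])
      r <- y - (p[4] + (p[1] - p[4]) / (1 + (x / cc)^p[2]))
      sum(w * r^2)
    }
    p0 <- c(start$a, start$b, log(start$c), start$d)
    opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    if (!is.finite(opt$value))
      stop(sprintf(
        "4PL fit failed to converge (start a=%.3g b=%.3g c=%.3g d=%.3g)",
        start$a, start$b, start$c, start$d))
    cf <- c(a = opt$par[1], b = opt$par[2], c = exp(opt$par[3]),
            d = opt$par[4])
    method <- "optim-nm"
  }
  fitted <- .fourpl_eval(x, cf)
  r2 <- 1 - sum(w * (y - fitted)^2) / ss_tot
  structure(list(coefficients = cf, r.squared = r2,
                 fitted.values = fitted, residuals = y - fitted,
                 data = data.frame(concentration = x, intensity = y),
                 degenerate = FALSE, method = method),
            class = "fourpl")
}

.fourpl_eval <- function(x, cf) {
  y <- cf["d"] + (cf["a"] - cf["d"]) / (1 + (x / cf["c"])^cf["b"])
  # limit at x = 0 is a for b > 0 (and d for b < 0); (0/c)^b is 0 or Inf
  y[x == 0] <- if (cf["b"] > 0) cf["a"] else cf["d"]
  unname(y)
}

#' @export
print.fourpl <- function(x, ...) {
  cf <- x$coefficients
  cat("Four-parameter logistic standard curve\n")
  cat(sprintf("  y = d + (a - d) / (1 + (x/c)^b)\n"))
  cat(sprintf("  a = %.6g   b = %.6g   c = %.6g   d = %.6g\n",
              cf["a"], cf["b"], cf["c"], cf["d"]))
  cat(sprintf("  R-squared: %.6f   (%s%s)\n", x$r.squared, x$method,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @export
coef.fourpl <- function(object, ...) object$coefficients

#' @export
residuals.fourpl <- function(object, ...) object$residuals

#' Predict intensity from concentration (or invert)
#'
#' @param object a `fourpl` fit.
#' @param newdata numeric vector of concentrations (intensities when
#'   `type = "concentration"`); defaults to the training concentrations.
#' @param type `"intensity"` (forward, default) or `"concentration"`
#'   (closed-form inverse, see [invert_4pl()]).
#' @param ... unused.
#' @export
predict.fourpl <- function(object, newdata = NULL,
                           type = c("intensity", "concentration"), ...) {
  type <- match.arg(type)
  if (type == "concentration")
    return(invert_4pl(object, newdata))
  if (is.null(newdata)) newdata <- object$data$concentration
  .fourpl_eval(as.numeric(newdata), object$coefficients)
}

#' @export
plot.fourpl <- function(x, ...) {
  d <- x$data
  pos <- d$concentration > 0
  xs <- exp(seq(log(min(d$concentration[pos])) - 1,
                log(max(d$concentration)) + 1, length.out = 200))
  graphics::plot(d$concentration[pos], d$intensity[pos], log = "x",
                 xlab = "concentration", ylab = "intensity",
                 main = sprintf("4PL fit (R² = %.4f)", x$r.squared),
                 ...)
  graphics::lines(xs, .fourpl_eval(xs, x$coefficients))
  invisible(x)
}

#' Invert a 4PL curve: concentration from intensity
#'
#' Closed-form inverse `x = c * ((a - y)/(y - d))^(1/b)`.  Intensities
#' outside the open interval between the fitted asymptotes cannot be
#' mapped back; they return `NA` and are marked in the
#' `"out_of_range"` attribute (a flagged result, not an error).
#'
#' @param curve a `fourpl` fit.
#' @param intensity numeric vector of measured intensities.
#' @return numeric vector of concentrations with attribute
#'   `out_of_range` (logical vector).
#' @export
invert_4pl <- function(curve, intensity) {
  cf <- curve$coefficients
  y <- as.numeric(intensity)
  lo <- min(cf["a"], cf["d"]); hi <- max(cf["a"], cf["d"])
  oor <- !(y > lo & y < hi)
  ratio <- (cf["a"] - y) / (y - cf["d"])
  x <- ifelse(oor, NA_real_, cf["c"] * ratio^(1 / cf["b"]))
  structure(unname(x), out_of_range = oor)
}

#' Aggregate replicate spot measurements per analyte
#'
#' Mean and coefficient of variation of the net intensities over the
#' unflagged replicates of each analyte (flagged = missing, saturated or
#' low-SNR).  Analytes with no unflagged replicate are reported with
#' `NA` mean and `missing = TRUE`.
#'
#' @param measurements data.frame from [process_well()] (one well).
#' @return data.frame: `analyte`, `n`, `mean_net`, `cv`, `missing`.
#' @export
aggregate_replicates <- function(measurements) {
  tests <- measurements[measurements$role == "test", , drop = FALSE]
  ok <- !tests$missing & !tests$saturated & !tests$low_snr &
    !is.na(tests$net)
  analytes <- unique(tests$analyte)
  res <- lapply(analytes, function(a) {
    v <- tests$net[ok & tests$analyte == a]
    if (!length(v))
      return(data.frame(analyte = a, n = 0L, mean_net = NA_real_,
                        cv = NA_real_, missing = TRUE))
    m <- mean(v)
    cv <- if (length(v) > 1L && m != 0) stats::sd(v) / m else 0
    data.frame(analyte = a, n = length(v), mean_net = m, cv = cv,
               missing = FALSE)
  })
  do.call(rbind, res)
}

#' Normalize analyte intensities to the well's positive controls
#'
#' Divides each analyte's aggregated net intensity by the mean net
#' intensity of the well's positive-control spots (BSA-biotin), making
#' wells comparable across illumination and exposure differences.
#'
#' @param aggregated data.frame from [aggregate_replicates()].
#' @param measurements the same well's full measurement table (the
#'   positive-control rows are taken from here).
#' @return `aggregated` with an added `normalized` column.
#' @export
normalize_intensity <- function(aggregated, measurements) {
  pos <- measurements[measurements$role == "control_positive" &
                        !measurements$missing & !is.na(measurements$net), ]
  if (!nrow(pos) || mean(pos$net) <= 0)
    stop("normalization error: nonpositive or absent positive-control signal")
  aggregated$normalized <- aggregated$mean_net / mean(pos$net)
  aggregated
}

#' Quantify a panel against fitted standard curves
#'
#' Maps each analyte's aggregated net intensity to a concentration via
#' the matching 4PL curve ([invert_4pl()]); intensities outside the
#' curve's dynamic range yield `NA` concentration.
#'
#' @param aggregated data.frame from [aggregate_replicates()] (possibly
#'   with a `normalized` column).
#' @param curves named list of `fourpl` fits, names = analytes.
#' @param use `"mean_net"` (default) or `"normalized"`: which column to
#'   push through the curves.
#' @return `aggregated` with an added `concentration` column.
#' @export
quantify_panel <- function(aggregated, curves, use = "mean_net") {
  conc <- vapply(seq_len(nrow(aggregated)), function(i) {
    a <- aggregated$analyte[i]
    v <- aggregated[[use]][i]
    if (is.na(v) || is.null(curves[[a]])) return(NA_real_)
    invert_4pl(curves[[a]], v)[1]
  }, numeric(1))
  aggregated$concentration <- conc
  aggregated
}

#' Serialize fitted curves to JSON
#'
#' @param curves named list of `fourpl` fits.
#' @param path output file path.
#' @export
write_curves_json <- function(curves, path) {
  doc <- lapply(curves, function(f)
    c(as.list(f$coefficients), list(r_squared = f$r.squared)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_curves_json
#' @export
read_curves_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  lapply(doc, function(d) {
    cf <- c(a = d$a, b = d$b, c = d$c, d = d$d)
    structure(list(coefficients = cf, r.squared = d$r_squared,
                   fitted.values = NULL, residuals = NULL, data = NULL,
                   degenerate = FALSE, method = "deserialized"),
              class = "fourpl")
  })
}
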