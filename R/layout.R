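#' Declarative array layout
#'
#' An `array_layout` records which spots a well contains, their roles, and
#' where the dispensing robot printed them.  Positions are expressed in a
#' reference pixel space (`ref_width` x `ref_height`, defaulting to the
#' native 4056 x 3040 sensor raster); they are rescaled automatically when
#' a frame of a different size is analysed, and so is `search_range`.
#'
#' @param spots data.frame with columns `label`, `role` (one of
#'   `"control_positive"`, `"control_negative"`, `"test"`), `analyte`,
#'   `replicate`, `x`, `y`, `radius`.  Test spots carry `analyte` and
#'   `replicate`; controls carry `NA` for both.
#' @param n_rows number of printed rows (default 4).
#' @param anchor_labels ordered control labels whose centroids anchor the
#'   grid fit (default `C1`, `C2`, `C3`).
#' @param bound_labels pair of control labels bounding the test-spot
#'   region (default `C4`, `C7`).
#' @param search_range admissible lateral distance (reference pixels) of a
#'   test spot from the anchor-row axis, on either side (default 1200).
#' @param ref_width,ref_height reference raster size the coordinates are
#'   expressed in.
#' @return an `array_layout` object.
#' @seealso [default_layout()], [read_layout_json()]
#' @export
array_layout <- function(spots, n_rows = 4L,
                         anchor_labels = c("C1", "C2", "C3"),
                         bound_labels = c("C4", "C7"),
                         search_range = 1200,
                         ref_width = 4056, ref_height = 3040) {
  need <- c("label", "role", "analyte", "replicate", "x", "y", "radius")
  if (!is.data.frame(spots) || !all(need %in% names(spots)))
    stop("'spots' must be a data.frame with columns: ",
         paste(need, collapse = ", "))
  spots <- as.data.frame(spots)[, need]
  if (anyDuplicated(spots$label))
    stop("spot labels must be unique within a layout")
  ok_roles <- c("control_positive", "control_negative", "test")
  if (!all(spots$role %in% ok_roles))
    stop("spot roles must be one of: ", paste(ok_roles, collapse = ", "))
  is_test <- spots$role == "test"
  if (any(is_test & (is.na(spots$analyte) | is.na(spots$replicate))))
    stop("test spots must carry an analyte and a replicate index")
  if (any(!is_test & (!is.na(spots$analyte) | !is.na(spots$replicate))))
    stop("control spots must not carry an analyte or replicate")
  ctrl <- spots$label[!is_test]
  if (!all(anchor_labels %in% ctrl))
    stop("anchor_labels must name control spots present in the layout")
  if (length(bound_labels) != 2L || !all(bound_labels %in% ctrl))
    stop("bound_labels must name two control spots present in the layout")
  if (search_range <= 0) stop("search_range must be positive")
  structure(
    list(spots = spots, n_rows = as.integer(n_rows),
         anchor_labels = anchor_labels, bound_labels = bound_labels,
         search_range = search_range,
         ref_width = ref_width, ref_height = ref_height),
    class = "array_layout")
}

#' @export
print.array_layout <- function(x, ...) {
  tab <- table(x$spots$role)
  cat(sprintf(
    "<array_layout: %d spots (%s) in %d rows, ref %g x %g px>\n",
    nrow(x$spots),
    paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
    x$n_rows, x$ref_width, x$ref_height))
  invisible(x)
}

#' Default biomarker-microarray well layout
#'
#' Five analytes printed in triplicate (15 test spots) plus seven printed
#' controls, arranged in four rows on the reference 4056 x 3040 raster:
#'
#' * row 1: anchor controls C1, C2, C3;
#' * row 2: C4, one replicate of each analyte, C5;
#' * row 3: C6, second replicates;
#' * row 4: third replicates, C7.
#'
#' C1--C4 and C7 are positive controls (BSA-biotin); C5 and C6 are
#' negative controls (PBS).  C4 and C7 sit at opposite corners of the
#' test-spot region and bound the admissible search area.
#'
#' @param analytes character vector of five analyte names.
#' @return an [array_layout].
#' @export
default_layout <- function(analytes = c("VSIG4", "OPN", "VCAM1",
                                        "ALCAM", "TNFRSF1B")) {
  stopifnot(length(analytes) == 5L)
  rw <- 4056; rh <- 3040
  row_y <- round(c(0.25, 0.37, 0.49, 0.61) * rh)
  edge_x <- round(c(0.15, 0.85) * rw)
  test_x <- round(seq(0.25, 0.75, length.out = 5L) * rw)
  rad <- 48
  ctrl <- function(label, x, y, role)
    data.frame(label = label, role = role, analyte = NA_character_,
               replicate = NA_integer_, x = x, y = y, radius = rad)
  tests <- function(rep_i, y)
    data.frame(label = sprintf("%s-r%d", analytes, rep_i), role = "test",
               analyte = analytes, replicate = rep_i,
               x = test_x, y = y, radius = rad)
  spots <- rbind(
    ctrl("C1", edge_x[1], row_y[1], "control_positive"),
    ctrl("C2", round(0.5 * rw), row_y[1], "control_positive"),
    ctrl("C3", edge_x[2], row_y[1], "control_positive"),
    ctrl("C4", edge_x[1], row_y[2], "control_positive"),
    tests(1L, row_y[2]),
    ctrl("C5", edge_x[2], row_y[2], "control_negative"),
    ctrl("C6", edge_x[1], row_y[3], "control_negative"),
    tests(2L, row_y[3]),
    tests(3L, row_y[4]),
    ctrl("C7", edge_x[2], row_y[4], "control_positive"))
  rownames(spots) <- NULL
  array_layout(spots)
}

#' Read or write a layout as JSON
#'
#' The JSON document mirrors the [array_layout] fields: a `spots` array of
#' records plus the scalar settings.
#'
#' @param path file path.
#' @return [read_layout_json()] returns an [array_layout];
#'   [write_layout_json()] returns `path` invisibly.
#' @export
read_layout_json <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  doc <- jsonlite::fromJSON(path)
  spots <- as.data.frame(doc$spots)
  spots$analyte <- as.character(spots$analyte)
  spots$replicate <- as.integer(spots$replicate)
  array_layout(spots,
               n_rows = doc$n_rows %||% 4L,
               anchor_labels = doc$anchor_labels %||% c("C1", "C2", "C3"),
               bound_labels = doc$bound_labels %||% c("C4", "C7"),
               search_range = doc$search_range %||% 1200,
               ref_width = doc$ref_width %||% 4056,
               ref_height = doc$ref_height %||% 3040)
}

#' @rdname read_layout_json
#' @param layout an [array_layout].
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "array_layout"))
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
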