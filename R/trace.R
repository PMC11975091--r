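#' Boundary trace of an arterial ring specimen
#'
#' An ordered set of 2D points traced along the inner or outer border of a
#' ring / sector specimen. Coordinates are in mm after image-scale
#' application (see [scale_from_reference()]), or raw pixels before.
#'
#' @param points two-column matrix or data.frame of x/y coordinates, in trace
#'   order. At least 4 points; consecutive points must be distinct. For a
#'   closed (uncut) ring the closure is implicit: if the first point is
#'   repeated at the end it is dropped with a warning.
#' @param border `"inner"` or `"outer"`.
#' @param closed logical; `TRUE` for an uncut ring, `FALSE` for a radially
#'   cut segment.
#' @param units `"mm"` or `"px"`.
#' @return object of class `boundary_trace` with elements `points`, `border`,
#'   `closed`, `units`.
#' @examples
#' th <- seq(0, pi, length.out = 20)
#' tr <- boundary_trace(cbind(2 * cos(th), 2 * sin(th)), "inner")
#' @export
boundary_trace <- function(points, border = c("inner", "outer"),
                           closed = FALSE, units = c("mm", "px")) {
  border <- match.arg(border)
  units <- match.arg(units)
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("`points` must have exactly two columns (x, y)")
  storage.mode(pts) <- "double"
  if (anyNA(pts) || any(!is.finite(pts))) {
    stop("`points` contains missing or non-finite coordinates")
  }
  if (isTRUE(closed) && nrow(pts) > 1L &&
      all(pts[1L, ] == pts[nrow(pts), ])) {
    warning("closed trace repeats its first point; dropping the duplicate ",
            "(closure is implicit)")
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  if (nrow(pts) < 4L) stop("a boundary trace needs at least 4 points, got ",
                           nrow(pts))
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  if (any(d == 0)) {
    stop("duplicate consecutive points at index ", which(d == 0)[1L] + 1L)
  }
  structure(list(points = pts, border = border, closed = closed,
                 units = units),
            class = "boundary_trace")
}

#' @export
print.boundary_trace <- function(x, ...) {
  cat(sprintf("<boundary_trace> %s border, %s, %d points [%s]\n",
              x$border, if (x$closed) "closed ring" else "open segment",
              nrow(x$points), x$units))
  invisible(x)
}

#' Image scale from a reference object
#'
#' The mm-per-pixel scale of a specimen photograph, obtained from an object
#' of known physical size visible in the image (the plastic cylindrical tube
#' the specimen is glued to).
#'
#' @param measured_px measured extent of the reference object in pixels.
#' @param known_mm its known physical size in mm.
#' @return scale factor in mm per pixel.
#' @examples
#' scale_from_reference(500, 10) # 0.02 mm/px
#' @export
scale_from_reference <- function(measured_px, known_mm) {
  if (!is.numeric(measured_px) || length(measured_px) != 1L ||
      !is.finite(measured_px) || measured_px <= 0) {
    stop("`measured_px` must be a single positive number")
  }
  if (!is.numeric(known_mm) || length(known_mm) != 1L ||
      !is.finite(known_mm) || known_mm <= 0) {
    stop("`known_mm` must be a single positive number")
  }
  known_mm / measured_px
}

#' Apply an image scale to a pixel-space trace
#'
#' Multiplies both coordinate axes uniformly, converting pixels to mm.
#'
#' @param trace a [boundary_trace()] in pixel units.
#' @param scale mm per pixel, from [scale_from_reference()].
#' @return the trace with coordinates in mm.
#' @export
apply_scale <- function(trace, scale) {
  stopifnot(inherits(trace, "boundary_trace"))
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("`scale` must be a single positive number")
  }
  if (trace$units == "mm") warning("trace is already in mm; scaling anyway")
  trace$points <- trace$points * scale
  trace$units <- "mm"
  trace
}
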