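# Gauss-Legendre 7-point nodes/weights on [-1, 1]; exact for degree <= 13,
# ample for the speed of a cubic spline segment.
.gl_nodes <- c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972,
               0, 0.4058451513773972, 0.7415311855993945, 0.9491079123427585)
.gl_weights <- c(0.1294849661688697, 0.2797053914892766, 0.3818300505051189,
                 0.4179591836734694, 0.3818300505051189, 0.2797053914892766,
                 0.1294849661688697)

.speed <- function(curve, t) {
  d1 <- eval_spline(curve, t, 1L)
  sqrt(rowSums(d1^2))
}

# arc length of curve between parameters a < b by composite Gauss-Legendre
.arc_between <- function(curve, a, b, n_sub = 8L) {
  if (b <= a) return(0)
  edges <- seq(a, b, length.out = n_sub + 1L)
  h <- (b - a) / n_sub / 2
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  tq <- as.vector(outer(.gl_nodes * h, mids, `+`))
  sum(.speed(curve, tq) * rep(.gl_weights, times = n_sub)) * h
}

# cumulative arc-length table on a fine uniform parameter grid
.arclength_table <- function(curve, n_grid = 256L) {
  tg <- seq(0, 1, length.out = n_grid + 1L)
  h <- 1 / n_grid / 2
  mids <- (tg[-1L] + tg[-length(tg)]) / 2
  tq <- as.vector(outer(.gl_nodes * h, mids, `+`))
  sp <- matrix(.speed(curve, tq), nrow = 7L)
  seg <- colSums(sp * .gl_weights) * h
  list(t = tg, cum = c(0, cumsum(seg)), total = sum(seg))
}

# invert cumulative arc length: parameter t with arclength(0, t) = s
.param_at_arclength <- function(curve, tab, s, rel_tol = 1e-10) {
  total <- tab$total
  if (s <= 0) return(0)
  if (s >= total) return(1)
  i <- findInterval(s, tab$cum, rightmost.closed = TRUE)
  f <- function(t) tab$cum[i] + .arc_between(curve, tab$t[i], t) - s
  stats::uniroot(f, lower = tab$t[i], upper = tab$t[i + 1L],
                 tol = rel_tol, extendInt = "upX")$root
}

#' Total arc length of a boundary spline
#'
#' @param curve a `spline_curve`.
#' @return arc length in mm (over one period for closed curves).
#' @export
arc_length <- function(curve) {
  stopifnot(inherits(curve, "spline_curve"))
  .arclength_table(curve)$total
}

#' Resample a boundary spline at equidistant arc-length positions
#'
#' Places `n` points at equal arc-length spacing along the curve. Open
#' segments include both endpoints (`n - 1` equal arcs); closed rings get
#' `n` points spanning the full period (`n` equal arcs, the last one closed
#' by the chord back to the first point). Arc-length positions are found by
#' root-finding on the cumulative arc length.
#'
#' @param curve a `spline_curve` from [fit_boundary_spline()].
#' @param n number of points, at least 3; 40 by default.
#' @return object of class `resampled_boundary`: `points` (n x 2), `t`
#'   (parameter values), `polyline_length` (sum of chord lengths, mm),
#'   `arc_total` (true spline arc length, mm), `closed`, and the `source`
#'   curve.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 25)[-25]
#' tr <- boundary_trace(cbind(cos(th), sin(th)), "inner", closed = TRUE)
#' rb <- resample_equidistant(fit_boundary_spline(tr), 40)
#' rb$polyline_length  # 80 * sin(pi / 40), the regular 40-gon perimeter
#' @export
resample_equidistant <- function(curve, n = 40L) {
  stopifnot(inherits(curve, "spline_curve"))
  n <- as.integer(n)
  if (n < 3L) stop("`n` must be at least 3")
  tab <- .arclength_table(curve)
  L <- tab$total
  s_targets <- if (curve$closed) L * (seq_len(n) - 1L) / n
               else L * (seq_len(n) - 1L) / (n - 1L)
  tp <- vapply(s_targets, function(s) .param_at_arclength(curve, tab, s),
               numeric(1))
  pts <- eval_spline(curve, tp, 0L)
  rb <- structure(
    list(points = pts, t = tp, closed = curve$closed, n = n,
         arc_total = L, source = curve),
    class = "resampled_boundary")
  rb$polyline_length <- polyline_length(rb)
  rb
}

#' Polyline length of a resampled boundary
#'
#' Sum of Euclidean chord lengths between consecutive resampled points (plus
#' the closing chord for rings). This chord sum is the specimen-length
#' estimate; it is always below the true spline arc length.
#'
#' @param rb a `resampled_boundary`, or a plain two-column coordinate matrix
#'   (treated as an open polyline).
#' @return length in mm.
#' @export
polyline_length <- function(rb) {
  if (inherits(rb, "resampled_boundary")) {
    pts <- rb$points
    closed <- rb$closed
  } else {
    pts <- as.matrix(rb)
    closed <- FALSE
  }
  n <- nrow(pts)
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  if (closed) d <- c(d, sqrt(sum((pts[1L, ] - pts[n, ])^2)))
  if (any(d == 0)) warning("coincident consecutive points contribute zero length")
  sum(d)
}

#' @export
print.resampled_boundary <- function(x, ...) {
  cat(sprintf(
    "<resampled_boundary> %d equidistant points, polyline %.4f mm (arc %.4f mm)%s\n",
    x$n, x$polyline_length, x$arc_total, if (x$closed) ", closed" else ""))
  invisible(x)
}
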