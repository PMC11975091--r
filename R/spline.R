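#' @importFrom splines splineDesign
NULL

# Signed orientation of an ordered point set: shoelace area for closed
# traces, accumulated tangent turning for open ones. Returns +1 (CCW),
# -1 (CW) or 0 (degenerate / straight).
.trace_orientation <- function(pts, closed) {
  n <- nrow(pts)
  if (closed) {
    x <- pts[, 1L]; y <- pts[, 2L]
    a <- sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)
    return(sign(a))
  }
  v <- pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE]
  ang <- atan2(v[, 2L], v[, 1L])
  turn <- diff(ang)
  turn <- (turn + pi) %% (2 * pi) - pi
  s <- sum(turn)
  if (abs(s) < 1e-9) 0 else sign(s)
}

# Chord-length parameterization on [0, 1]. For closed curves the closing
# chord is included in the total, so parameters live on [0, 1).
.chord_params <- function(pts, closed) {
  n <- nrow(pts)
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  if (closed) d <- c(d, sqrt(sum((pts[1L, ] - pts[n, ])^2)))
  cs <- cumsum(c(0, d))
  cs[seq_len(n)] / cs[length(cs)]
}

# Extended knot vector + unfolded coefficient expansion for a periodic
# B-spline of degree k with independent coefficients c[1..m]: basis index
# j > m wraps to j - m. `inner` are the m knot positions in [0, 1).
.periodic_knots <- function(inner, k) {
  m <- length(inner)
  c(inner[(m - k + 1L):m] - 1, inner, inner[seq_len(k + 1L)] + 1)
}

.fold_periodic <- function(B, m, k) {
  # B has m + k columns; wrap the trailing k into the leading k
  for (j in seq_len(k)) B[, j] <- B[, j] + B[, m + j]
  B[, seq_len(m), drop = FALSE]
}

.unfold_coef <- function(coef, k) {
  rbind(coef, coef[seq_len(k), , drop = FALSE])
}

# de Boor averaging knots for open-curve interpolation at parameters t
.averaging_knots <- function(t, k) {
  n <- length(t)
  interior <- if (n > k + 1L) {
    vapply(seq_len(n - k - 1L),
           function(j) mean(t[(j + 1L):(j + k)]), numeric(1))
  } else numeric(0)
  c(rep(t[1L], k + 1L), interior, rep(t[n], k + 1L))
}

.fit_open <- function(pts, t, k, n_basis) {
  n <- nrow(pts)
  if (n_basis >= n) {            # interpolation
    knots <- .averaging_knots(t, k)
    B <- splines::splineDesign(knots, t, ord = k + 1L)
    coef <- solve(B, pts)
  } else {                       # least squares on quantile knots
    n_int <- n_basis - k - 1L
    interior <- if (n_int > 0L) {
      stats::quantile(t, probs = seq_len(n_int) / (n_int + 1L),
                      names = FALSE, type = 7)
    } else numeric(0)
    knots <- c(rep(t[1L], k + 1L), interior, rep(t[length(t)], k + 1L))
    B <- splines::splineDesign(knots, t, ord = k + 1L)
    coef <- qr.coef(qr(B), pts)
  }
  list(knots = knots, coef = coef)
}

.fit_closed <- function(pts, t, k, n_basis) {
  n <- nrow(pts)
  if (n_basis >= n) {            # periodic interpolation at the data params
    knots <- .periodic_knots(t, k)
    B <- splines::splineDesign(knots, t, ord = k + 1L)
    B <- .fold_periodic(B, n, k)
    coef <- solve(B, pts)
    m <- n
  } else {                       # periodic least squares on uniform knots
    m <- n_basis
    inner <- (seq_len(m) - 1L) / m
    knots <- .periodic_knots(inner, k)
    B <- splines::splineDesign(knots, t, ord = k + 1L)
    B <- .fold_periodic(B, m, k)
    coef <- qr.coef(qr(B), pts)
  }
  list(knots = knots, coef = .unfold_coef(coef, k))
}

#' Fit a parametric B-spline to a traced boundary
#'
#' Fits a planar parametric spline (x(t), y(t)) through or near the trace
#' points, using chord-length parameterization. With `smoothing = 0` the
#' curve interpolates every point; with `smoothing > 0` a least-squares
#' B-spline with as few uniformly placed knots as possible is used, knots
#' being added until the RMS Euclidean residual of the fit at the trace
#' points drops to `smoothing` (in the units of the trace, i.e. mm). The
#' smoothing value should therefore be set to the expected tracing noise.
#'
#' Traces are re-oriented counterclockwise before fitting, so curvature of a
#' lumen-convex boundary comes out positive. Closed traces get a periodic
#' fit, continuous in value and first two derivatives across the seam.
#'
#' @param trace a [boundary_trace()].
#' @param degree spline degree, `>= 2`; cubic (3) is the default and the
#'   minimal degree with continuous curvature.
#' @param smoothing nonnegative RMS residual tolerance in mm; 0 means
#'   interpolation.
#' @return object of class `spline_curve`; evaluate with [eval_spline()].
#' @examples
#' th <- seq(0, 2 * pi, length.out = 21)[-21]
#' tr <- boundary_trace(cbind(cos(th), sin(th)), "inner", closed = TRUE)
#' cv <- fit_boundary_spline(tr)
#' @export
fit_boundary_spline <- function(trace, degree = 3L, smoothing = 0) {
  stopifnot(inherits(trace, "boundary_trace"))
  k <- as.integer(degree)
  if (k < 2L) stop("`degree` must be at least 2")
  if (!is.numeric(smoothing) || smoothing < 0) {
    stop("`smoothing` must be a nonnegative number")
  }
  pts <- trace$points
  n <- nrow(pts)
  if (n < k + 2L) {
    stop("too few points (", n, ") for a degree-", k,
         " spline; need at least ", k + 2L)
  }
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  if (any(d == 0)) {
    stop("duplicate consecutive points at index ", which(d == 0)[1L] + 1L)
  }

  if (.trace_orientation(pts, trace$closed) < 0) pts <- pts[n:1L, , drop = FALSE]
  t <- .chord_params(pts, trace$closed)

  fit_at <- function(nb) {
    if (trace$closed) .fit_closed(pts, t, k, nb) else .fit_open(pts, t, k, nb)
  }
  min_basis <- k + 2L
  if (smoothing == 0) {
    fit <- fit_at(n)
    n_basis <- n
  } else {
    # grow the basis until the fit is within the noise tolerance
    fit <- NULL
    for (nb in min_basis:n) {
      fit <- fit_at(nb)
      res <- .fit_residual_rms(fit, pts, t, k, trace$closed)
      n_basis <- nb
      if (res <= smoothing) break
    }
  }
  curve <- structure(
    list(knots = fit$knots, coef = fit$coef, degree = k,
         closed = trace$closed, smoothing = smoothing,
         n_basis = n_basis, border = trace$border),
    class = "spline_curve")
  curve$residual_rms <- .fit_residual_rms(fit, pts, t, k, trace$closed)
  curve
}

.fit_residual_rms <- function(fit, pts, t, k, closed) {
  # for closed fits coef is already unfolded to match the extended basis
  B <- splines::splineDesign(fit$knots, t, ord = k + 1L)
  sqrt(mean(rowSums((B %*% fit$coef - pts)^2)))
}

#' Evaluate a fitted boundary spline
#'
#' @param curve a `spline_curve` from [fit_boundary_spline()].
#' @param t parameter values; the curve lives on `[0, 1]`. For closed curves
#'   `t` is taken modulo 1, for open curves it is clamped to `[0, 1]`.
#' @param deriv derivative order: 0 (position), 1 or 2.
#' @return numeric matrix `length(t)` x 2 of (x, y) values or derivatives
#'   with respect to `t`.
#' @export
eval_spline <- function(curve, t, deriv = 0L) {
  stopifnot(inherits(curve, "spline_curve"))
  deriv <- as.integer(deriv)
  if (deriv < 0L || deriv > curve$degree) {
    stop("`deriv` must be between 0 and the spline degree")
  }
  tt <- if (curve$closed) t %% 1 else pmin(pmax(t, 0), 1)
  B <- splines::splineDesign(curve$knots, tt, ord = curve$degree + 1L,
                             derivs = rep(deriv, length(tt)))
  unname(B %*% curve$coef)
}

#' @export
print.spline_curve <- function(x, ...) {
  cat(sprintf(
    "<spline_curve> degree %d, %s, %d basis functions, residual RMS %.2e\n",
    x$degree, if (x$closed) "periodic" else "open", x$n_basis,
    x$residual_rms))
  invisible(x)
}
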