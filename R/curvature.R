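#' Local curvature profile of a boundary spline
#'
#' Evaluates the signed local curvature
#' \deqn{\kappa = \frac{x'y'' - y'x''}{(x'^2 + y'^2)^{3/2}}}
#' analytically from the spline derivatives at the interior resampled points
#' (the first and last of the `n` equidistant points are excluded, giving
#' `n - 2` values — 38 for the default 40). Traces are oriented
#' counterclockwise at fit time, so a lumen-convex boundary has positive
#' curvature throughout; residual-deformation behaviour is carried by the
#' change of the mean curvature between time states.
#'
#' The mean curvature is the arithmetic mean of the local values and the
#' reported mean radius is its reciprocal. The alternative averaging order
#' (mean of the local radii) is also returned as `radius_mean_of_local` for
#' comparison, but the curvature mean is the canonical summary.
#'
#' @param curve the `spline_curve` the boundary was resampled from.
#' @param rb the matching `resampled_boundary`.
#' @return object of class `curvature_profile`: `kappa` (1/mm at the
#'   interior points), `t` (their parameters), `mean_kappa`, `mean_radius`
#'   (= 1/mean_kappa), `radius_mean_of_local`.
#' @export
local_curvature <- function(curve, rb) {
  stopifnot(inherits(curve, "spline_curve"),
            inherits(rb, "resampled_boundary"))
  idx <- 2:(rb$n - 1L)
  tt <- rb$t[idx]
  d1 <- eval_spline(curve, tt, 1L)
  d2 <- eval_spline(curve, tt, 2L)
  sp2 <- rowSums(d1^2)
  if (any(sp2 < 1e-16)) {
    stop("singular parameterization: zero first derivative at parameter t = ",
         signif(tt[which(sp2 < 1e-16)[1L]], 6))
  }
  kappa <- (d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]) / sp2^1.5
  mk <- mean(kappa)
  structure(
    list(kappa = kappa, t = tt,
         mean_kappa = mk,
         mean_radius = if (abs(mk) > .Machine$double.eps) 1 / mk else NA_real_,
         radius_mean_of_local = if (all(abs(kappa) > .Machine$double.eps))
           mean(1 / kappa) else NA_real_),
    class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf("<curvature_profile> %d points, mean kappa %.4f 1/mm (R = %.3f mm)\n",
              length(x$kappa), x$mean_kappa, x$mean_radius))
  invisible(x)
}

#' Radius of curvature from curvature
#'
#' `R = 1 / kappa`, in mm for curvature in 1/mm. Vectorized.
#'
#' @param kappa local curvature(s), 1/mm; must be nonzero.
#' @return radius (mm).
#' @examples
#' radius_of_curvature(0.5)   # 2 mm
#' radius_of_curvature(0.362) # 2.76 mm, a typical uncut-ring inner boundary
#' @export
radius_of_curvature <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) == 0L) {
    stop("`kappa` must be numeric")
  }
  if (any(!is.finite(kappa)) || any(kappa == 0)) {
    stop("zero curvature has infinite radius; handle straight segments upstream")
  }
  1 / kappa
}

# total signed tangent turning along the curve, radians; winding past a full
# turn accumulates rather than wrapping
.total_turning <- function(curve, n_grid = 720L) {
  tg <- seq(0, 1, length.out = n_grid + 1L)
  if (curve$closed) tg <- tg * (1 - 1e-12)
  d1 <- eval_spline(curve, tg, 1L)
  ang <- atan2(d1[, 2L], d1[, 1L])
  dd <- diff(ang)
  dd <- (dd + pi) %% (2 * pi) - pi
  sum(dd)
}

#' Opening angle of a cut segment
#'
#' The opening angle Phi of a radially cut ring segment: the angle between
#' two rays from the arc-length midpoint of the (inner) boundary to its two
#' endpoints. The sign comes from the enclosed arc angle theta (the total
#' tangent turning of the boundary): `Phi > 0` when the segment has opened
#' (theta < 360 deg) and `Phi < 0` when it has closed past a full circle
#' (theta > 360 deg, cut ends overlapping). For a circular arc
#' `Phi = 180 - theta/2` exactly.
#'
#' @param inner_rb `resampled_boundary` of the inner boundary of an open
#'   (cut) segment with at least 5 points.
#' @return signed opening angle in degrees.
#' @examples
#' th <- seq(0, pi, length.out = 21) # semicircular segment
#' tr <- boundary_trace(cbind(cos(th), sin(th)), "inner")
#' rb <- resample_equidistant(fit_boundary_spline(tr), 40)
#' opening_angle(rb) # 90 degrees
#' @export
opening_angle <- function(inner_rb) {
  stopifnot(inherits(inner_rb, "resampled_boundary"))
  if (inner_rb$closed) {
    stop("opening angle undefined for uncut ring")
  }
  if (inner_rb$n < 5L) stop("need at least 5 resampled points")
  curve <- inner_rb$source
  tab <- .arclength_table(curve)
  t_mid <- .param_at_arclength(curve, tab, tab$total / 2)
  vertex <- drop(eval_spline(curve, t_mid, 0L))
  p1 <- inner_rb$points[1L, ]
  p2 <- inner_rb$points[inner_rb$n, ]
  v1 <- p1 - vertex
  v2 <- p2 - vertex
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  phi_mag <- if (n1 < 1e-9 || n2 < 1e-9) 0 else {
    acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
  }
  theta_deg <- abs(.total_turning(curve)) * 180 / pi
  if (theta_deg > 360) -phi_mag else phi_mag
}

#' Curvature of the circular arc equivalent to an opening angle
#'
#' Different studies define the opening angle differently; assuming the
#' boundary is a circular arc, an opening angle plus the boundary length can
#' be converted to the arc curvature for cross-study comparison. The arc
#' angle is `theta = 360 - 2 * phi` degrees, so `kappa = theta_rad / length`.
#'
#' @param length boundary length in mm, positive.
#' @param phi signed opening angle in degrees, `< 180`.
#' @return equivalent arc curvature in 1/mm.
#' @examples
#' circular_equivalent_curvature(2 * pi, 0)  # full unit circle: 1
#' circular_equivalent_curvature(pi, 90)     # unit semicircle: 1
#' @export
circular_equivalent_curvature <- function(length, phi) {
  if (!is.numeric(length) || length <= 0) stop("`length` must be positive")
  if (!is.numeric(phi) || phi > 180) {
    stop("`phi` must not exceed 180 degrees (arc angle would be negative)")
  }
  if (phi == 180) return(0)
  (360 - 2 * phi) * pi / 180 / length
}
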