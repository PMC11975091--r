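# geometry fixtures built in code: points on circles/arcs/ellipses and an
# independent curvature oracle (Menger / circumscribed-circle curvature),
# used to cross-check the spline-derivative curvature path

circle_pts <- function(R = 1, theta_deg = 360, n = 20, center = c(0, 0),
                       start = 0, ccw = TRUE) {
  closed <- isTRUE(all.equal(theta_deg, 360))
  th <- if (closed) {
    seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  } else {
    seq(0, theta_deg * pi / 180, length.out = n)
  }
  if (!ccw) th <- -th
  cbind(center[1] + R * cos(start + th), center[2] + R * sin(start + th))
}

circle_trace <- function(R = 1, theta_deg = 360, n = 20, border = "inner",
                         ...) {
  boundary_trace(circle_pts(R, theta_deg, n, ...), border,
                 closed = isTRUE(all.equal(theta_deg, 360)))
}

ellipse_pts <- function(a = 2, b = 1, n = 40, closed = TRUE) {
  th <- if (closed) seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
        else seq(0, pi, length.out = n)
  cbind(a * cos(th), b * sin(th))
}

# Menger curvature of the circumscribed circle through three points
menger_kappa <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p1)^2))
  b <- sqrt(sum((p3 - p2)^2))
  c <- sqrt(sum((p3 - p1)^2))
  area2 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
    (p3[1] - p1[1]) * (p2[2] - p1[2])
  2 * area2 / (a * b * c)
}

# finite-difference curvature profile of a dense point polyline
fd_curvature <- function(pts) {
  n <- nrow(pts)
  vapply(2:(n - 1), function(i) {
    menger_kappa(pts[i - 1, ], pts[i, ], pts[i + 1, ])
  }, numeric(1))
}

measure_trace <- function(trace, smoothing = 0, n = 40) {
  cv <- fit_boundary_spline(trace, smoothing = smoothing)
  rb <- resample_equidistant(cv, n)
  list(curve = cv, rb = rb, profile = local_curvature(cv, rb))
}
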