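test_that("circle oracle: mean curvature is 1/R across radii", {
  for (R in c(0.5, 1, 2, 5, 10)) {
    # open arcs at manual-trace density are superconvergent
    m <- measure_trace(circle_trace(R, theta_deg = 180, n = 20))
    expect_equal(m$profile$mean_kappa, 1 / R, tolerance = 1e-3)
    expect_equal(m$profile$mean_radius, R, tolerance = 1e-3)
    # closed rings at the 20-point manual density carry a small aliasing
    # bias (evaluation points vs knots); stays comfortably below 1%
    mc <- measure_trace(circle_trace(R, n = 20))
    expect_equal(mc$profile$mean_kappa, 1 / R, tolerance = 1e-2)
    # densely traced closed rings reach the 0.1% level too
    md <- measure_trace(circle_trace(R, n = 60))
    expect_equal(md$profile$mean_kappa, 1 / R, tolerance = 1e-3)
  }
})

test_that("spline curvature agrees with the Menger finite-difference oracle", {
  # independent route: three-point circumscribed-circle curvature of points
  # evaluated on the fitted curve vs the analytic-derivative formula at the
  # same parameters
  shapes <- list(
    boundary_trace(ellipse_pts(a = 2, b = 1, n = 40), "inner",
                   closed = TRUE),
    circle_trace(R = 3, theta_deg = 250, n = 24))
  h <- 1e-4
  for (tr in shapes) {
    cv <- fit_boundary_spline(tr)
    rb <- resample_equidistant(cv, 40)
    cp <- local_curvature(cv, rb)
    for (j in seq_along(cp$t)) {
      t0 <- cp$t[j]
      p3 <- eval_spline(cv, c(t0 - h, t0, t0 + h))
      kap_fd <- abs(menger_kappa(p3[1, ], p3[2, ], p3[3, ]))
      expect_equal(cp$kappa[j], kap_fd, tolerance = 0.01)
    }
  }
})

test_that("ellipse extremes match the closed forms", {
  a <- 2; b <- 1
  tr <- boundary_trace(ellipse_pts(a, b, n = 60), "inner", closed = TRUE)
  cv <- fit_boundary_spline(tr)
  rb <- resample_equidistant(cv, 80)
  cp <- local_curvature(cv, rb)
  pts <- rb$points[2:(rb$n - 1), ]
  # compare against the true ellipse curvature at the matched parametric
  # angle; tightest curvature a/b^2 = 2 at the vertex, b/a^2 at the
  # co-vertex. A 60-point trace carries ~1% interpolation error at the
  # vertex, so allow 2%.
  tha <- atan2(pts[, 2] / b, pts[, 1] / a)
  ktrue <- a * b / (a^2 * sin(tha)^2 + b^2 * cos(tha)^2)^1.5
  expect_lt(max(abs(cp$kappa / ktrue - 1)), 0.02)
  # extremes attained at the right places
  expect_equal(max(cp$kappa), a / b^2, tolerance = 2e-2)
  expect_equal(min(cp$kappa), b / a^2, tolerance = 2e-2)
  expect_lt(abs(pts[which.max(cp$kappa), 2]), 0.1)  # on the major axis
  expect_lt(abs(pts[which.min(cp$kappa), 1]), 0.1)  # on the minor axis
})

test_that("radius of curvature is the pointwise reciprocal", {
  m <- measure_trace(circle_trace(R = 2, theta_deg = 200, n = 20))
  r <- radius_of_curvature(m$profile$kappa)
  expect_equal(r * m$profile$kappa, rep(1, length(r)))
  expect_equal(m$profile$mean_radius * m$profile$mean_kappa, 1)
  expect_equal(radius_of_curvature(0.5), 2)
  expect_equal(radius_of_curvature(0.362), 2.762431, tolerance = 1e-6)
  expect_error(radius_of_curvature(0), "infinite radius")
  expect_error(radius_of_curvature(c(0.5, 0)), "infinite radius")
})

test_that("both averaging orders are available", {
  # on an ellipse mean-of-curvatures and 1/mean-of-radii genuinely differ
  tr <- boundary_trace(ellipse_pts(a = 2, b = 1, n = 40), "inner",
                       closed = TRUE)
  cv <- fit_boundary_spline(tr)
  cp <- local_curvature(cv, resample_equidistant(cv, 40))
  expect_gt(cp$radius_mean_of_local, cp$mean_radius)
})
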