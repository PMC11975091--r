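test_that("interpolating fit passes through exact circle points", {
  tr <- circle_trace(R = 2, n = 20)
  cv <- fit_boundary_spline(tr, smoothing = 0)
  te <- seq(0, 1, length.out = 400)
  p <- eval_spline(cv, te)
  rad <- sqrt(rowSums(p^2))
  expect_lt(max(abs(rad - 2)), 0.01)  # within 0.01 mm of the true circle
  expect_lt(cv$residual_rms, 1e-10)   # interpolation
})

test_that("collinear points give a curvature-free straight fit", {
  tr <- boundary_trace(cbind(seq(0, 9), rep(1, 10)), "inner")
  m <- measure_trace(tr)
  expect_lt(max(abs(m$profile$kappa)), 1e-8)
})

test_that("smoothing fit averages out tracing jitter", {
  set.seed(42)
  pts <- circle_pts(R = 2, n = 20) + matrix(rnorm(40, sd = 0.02), ncol = 2)
  tr <- boundary_trace(pts, "inner", closed = TRUE)
  cv <- fit_boundary_spline(tr, smoothing = 0.03)
  rb <- resample_equidistant(cv, 40)
  ctr <- colMeans(rb$points)
  rad <- sqrt(rowSums(sweep(rb$points, 2, ctr)^2))
  expect_lt(sqrt(mean((rad - 2)^2)), 0.02)  # RMS within the jitter sd
  expect_lt(cv$n_basis, 20)                 # genuinely fewer dof than points
})

test_that("fit errors are explicit", {
  tr <- boundary_trace(circle_pts(n = 4, theta_deg = 90), "inner")
  expect_error(fit_boundary_spline(tr, degree = 3), "too few points")
  expect_error(fit_boundary_spline(tr, degree = 1), "at least 2")
  expect_error(fit_boundary_spline(tr, degree = 3, smoothing = -1),
               "nonnegative")
  expect_silent(fit_boundary_spline(tr, degree = 2))
})

test_that("periodic fits are smooth across the seam", {
  tr <- circle_trace(R = 1.5, n = 24)
  cv <- fit_boundary_spline(tr)
  eps <- 1e-9
  for (d in 0:2) {
    lo <- eval_spline(cv, eps, d)
    hi <- eval_spline(cv, 1 - eps, d)
    expect_equal(lo, hi, tolerance = 1e-5)
  }
})

test_that("reversing the trace changes neither |kappa|, length nor phi", {
  th <- seq(0, 1.2 * pi, length.out = 20)
  pts <- cbind(2 * cos(th), 2 * sin(th))
  m1 <- measure_trace(boundary_trace(pts, "inner"))
  m2 <- measure_trace(boundary_trace(pts[20:1, ], "inner"))
  expect_equal(m1$profile$mean_kappa, m2$profile$mean_kappa,
               tolerance = 1e-8)
  expect_equal(m1$rb$polyline_length, m2$rb$polyline_length,
               tolerance = 1e-8)
  expect_equal(opening_angle(m1$rb), opening_angle(m2$rb),
               tolerance = 1e-6)
})

test_that("scaling coordinates scales lengths by s, curvature by 1/s", {
  s <- 3.7
  th <- seq(0, 1.5 * pi, length.out = 20)
  pts <- cbind(2 * cos(th), 2 * sin(th))
  m1 <- measure_trace(boundary_trace(pts, "inner"))
  m2 <- measure_trace(boundary_trace(pts * s, "inner"))
  expect_equal(m2$rb$polyline_length, s * m1$rb$polyline_length,
               tolerance = 1e-8)
  expect_equal(m2$profile$mean_kappa, m1$profile$mean_kappa / s,
               tolerance = 1e-6)
  expect_equal(opening_angle(m2$rb), opening_angle(m1$rb),
               tolerance = 1e-4)
})
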