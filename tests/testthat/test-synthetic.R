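test_that("state truth follows the closed forms", {
  sp <- synthetic_spec(mid_radius = 3, thickness = 0.6,
                       kappa_ratio_inf = 0.8, tau_h = 2,
                       membrane_strain_inf_pct = -3.8, seed = 1)
  tr <- state_truth(sp, "ring")
  expect_true(tr$closed)
  expect_equal(tr$kappa_in, 1 / (3 - 0.3))
  expect_equal(tr$kappa_out, 1 / (3 + 0.3))
  expect_equal(tr$length_in, 2 * pi * 2.7)
  expect_true(is.na(tr$phi_deg))
  t22 <- state_truth(sp, "cut_22h")
  decay <- exp(-22 / 2)
  kmid <- (0.8 + 0.2 * decay) / 3
  expect_equal(t22$kappa_mid, kmid)
  expect_equal(t22$membrane_strain_pct, -3.8 * (1 - decay))
  expect_equal(t22$theta_deg,
               2 * pi * 3 * (1 - 3.8 * (1 - decay) / 100) * kmid * 180 / pi)
  expect_equal(t22$phi_deg, 180 - t22$theta_deg / 2)
  expect_error(state_truth(sp, "nonsense"), "unknown time state")
})

test_that("relaxation limits behave", {
  fast <- synthetic_spec(3, 0.6, kappa_ratio_inf = 0.7, tau_h = 1e-9,
                         seed = 1)
  states <- c("cut_30min", "cut_16h", "cut_22h")
  k_fast <- vapply(states, function(s) state_truth(fast, s)$kappa_mid,
                   numeric(1))
  expect_equal(unname(k_fast), rep(0.7 / 3, 3))
  slow <- synthetic_spec(3, 0.6, kappa_ratio_inf = 0.7, tau_h = 1e9,
                         seed = 1)
  k_slow <- vapply(states, function(s) state_truth(slow, s)$kappa_mid,
                   numeric(1))
  expect_equal(unname(k_slow), rep(1 / 3, 3), tolerance = 1e-6)
  # MI default: change essentially complete before 16 h
  mi <- synthetic_spec(3, 0.6, kappa_ratio_inf = 0.67, tau_h = 0.2, seed = 1)
  k0 <- state_truth(mi, "ring")$kappa_mid
  kinf <- 0.67 * k0
  d <- abs(state_truth(mi, "cut_16h")$kappa_mid -
             state_truth(mi, "cut_22h")$kappa_mid)
  expect_lt(d, 0.05 * abs(k0 - kinf))
})

test_that("noise-free sector traces are recovered by the pipeline", {
  sp <- synthetic_spec(mid_radius = 3, thickness = 0.6, noise_sd = 0,
                       n_trace_points = 60, seed = 5)
  ring <- generate_sector_trace(sp, "ring")
  g <- segment_geometry(ring$inner, ring$outer)
  expect_equal(g$inner$curvature$mean_kappa, ring$truth$kappa_in,
               tolerance = 1e-3)
  expect_true(is.na(g$opening_angle_deg))
  expect_error(opening_angle(g$inner$resampled), "uncut")

  half <- synthetic_spec(3, 0.6, arc_angle = 180, noise_sd = 0, seed = 5)
  st <- generate_sector_trace(half, "ring")
  gh <- segment_geometry(st$inner, st$outer)
  expect_equal(gh$opening_angle_deg, 90, tolerance = 0.1)

  over <- synthetic_spec(3, 0.6, arc_angle = 400, noise_sd = 0, seed = 5)
  so <- generate_sector_trace(over, "ring")
  go <- suppressWarnings(segment_geometry(so$inner, so$outer))
  expect_equal(go$opening_angle_deg, -20, tolerance = 0.1)
})

test_that("generation is reproducible and seed-hierarchical", {
  sp <- synthetic_spec(3, 0.5, seed = 42)
  a <- generate_sector_trace(sp, "cut_16h")
  b <- generate_sector_trace(sp, "cut_16h")
  expect_identical(a$inner$points, b$inner$points)
  other <- generate_sector_trace(sp, "cut_22h")
  expect_false(identical(a$inner$points[1, ], other$inner$points[1, ]))
  # generator must not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(generate_sector_trace(sp, "ring")); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("specimen schedules follow the protocols", {
  sp <- synthetic_spec(3, 0.5, seed = 2)
  r2 <- generate_specimen_timeseries(sp, 2, "MI")
  expect_equal(names(r2$states),
               c("ring", "cut_30min", "cut_16h", "cut_22h"))
  r1 <- generate_specimen_timeseries(sp, 1, "A", patient_id = "P3")
  expect_equal(names(r1$states), c("ring", "separate", "separate_6h"))
  ri <- generate_specimen_timeseries(sp, 1, "I")
  expect_equal(names(ri$states), c("ring", "cut_30min", "cut_16h"))
  expect_error(generate_specimen_timeseries(sp, 2, "MI",
                                            states = "separate"),
               "not in protocol")
  expect_equal(length(r2$thickness_readings), 3L)
  expect_equal(r2$thickness_mean, 0.5, tolerance = 0.05)
})

test_that("cohort generation is reproducible with valid truth", {
  cfg <- cohort_config(n_patients = 2, seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(
    c1$specimens[[1]]$states$ring$inner$points,
    c2$specimens[[1]]$states$ring$inner$points)
  tt <- c1$truth
  expect_true(all(c("specimen_id", "layer", "protocol", "time_state",
                    "kappa_in", "kappa_out", "length_in", "length_out",
                    "phi_deg", "a_pct", "f") %in% names(tt)))
  expect_true(all(tt$kappa_in > tt$kappa_out))
  expect_true(all(tt$length_in < tt$length_out))
  expect_true(all(is.na(tt$phi_deg) == tt$closed))
  expect_error(
    generate_cohort(cohort_config(
      n_patients = 1,
      layer_params = list(MI = list(thickness = c(mean = 9, sd = 0.1))))),
    "infeasible")
})

test_that("a noise-free clean cohort is recovered within 0.5%", {
  cfg <- cohort_config(n_patients = 2, noise_sd = 0,
                       imperfect_separation = FALSE, seed = 3,
                       include_intact = FALSE)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  res <- run_pipeline(run_config(paths[["traces"]], paths[["metadata"]],
                                 smoothing = 0))
  m <- merge(res$per_specimen, co$truth, by = c("specimen_id", "time_state"))
  expect_equal(nrow(m), nrow(co$truth))
  expect_lt(max(abs(m$kappa_in.x / m$kappa_in.y - 1)), 0.005)
  expect_lt(max(abs(m$kappa_out.x / m$kappa_out.y - 1)), 0.005)
  expect_lt(max(abs(m$length_in.x / m$length_in.y - 1)), 0.005)
  expect_lt(max(abs(m$length_out.x / m$length_out.y - 1)), 0.005)
  op <- !is.na(m$phi_deg.y)
  expect_lt(max(abs(m$phi_deg.x[op] - m$phi_deg.y[op])), 0.2)
})
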