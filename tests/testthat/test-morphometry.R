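test_that("mean_thickness averages three positive readings", {
  expect_equal(mean_thickness(c(0.9, 0.9, 0.9)), 0.9)
  expect_equal(mean_thickness(c(0.5, 0.6, 0.7)), 0.6)
  expect_error(mean_thickness(c(0.5, -0.1, 0.6)), "positive")
  expect_error(mean_thickness(c(0.5, 0.6)), "3 thickness readings")
  expect_error(mean_thickness(c(0.5, NA, 0.6)), "positive")
})

test_that("adventitia percentage matches the cohort worked examples", {
  expect_equal(adventitia_percentage(0.36, 0.60), 0.375)
  expect_equal(round(adventitia_percentage(0.36, 0.60), 2), 0.38)
  expect_equal(round(adventitia_percentage(0.47, 0.70), 2), 0.40)
  for (t in c(0.1, 0.5, 2)) {
    expect_equal(adventitia_percentage(t, t), 0.5)
  }
  # A% and the media share sum to one
  expect_equal(adventitia_percentage(0.36, 0.60) +
                 adventitia_percentage(0.60, 0.36), 1)
  expect_error(adventitia_percentage(0, 0.6), "positive")
})

test_that("boundary strain is the signed percent length change", {
  expect_equal(boundary_strain(100, 106.12)$strain_pct, 6.12)
  expect_equal(boundary_strain(20, 20)$strain_pct, 0)
  expect_equal(boundary_strain(104, 100)$strain_pct, -100 * 4 / 104)
  expect_error(boundary_strain(100, 106, specimen_id = list("s1", "s2")),
               "different specimens")
  expect_error(boundary_strain(-1, 5), "positive")
  # round-trip: swapping reference and final multiplies out to 1
  e1 <- boundary_strain(104, 100)$strain_pct
  e2 <- boundary_strain(100, 104)$strain_pct
  expect_equal((1 + e1 / 100) * (1 + e2 / 100), 1)
})

test_that("membrane/bending decomposition reconstructs the strains", {
  d <- strain_decomposition(6, -6)
  expect_equal(d$membrane_pct, 0)
  expect_equal(d$bending_pct, 6)
  d2 <- strain_decomposition(-3.80, -3.81)
  expect_equal(d2$membrane_pct, -3.805)
  expect_equal(d2$bending_pct, 0.005)
  d3 <- strain_decomposition(6.18, -4.18)
  expect_equal(d3$membrane_pct, 1.00)
  expect_equal(d3$bending_pct, 5.18)
  # exact reconstruction identity on random strains
  set.seed(7)
  for (i in 1:20) {
    ei <- rnorm(1, 0, 5); eo <- rnorm(1, 0, 5)
    d <- strain_decomposition(ei, eo)
    expect_lt(abs(d$membrane_pct + d$bending_pct - ei), 1e-12)
    expect_lt(abs(d$membrane_pct - d$bending_pct - eo), 1e-12)
  }
})

test_that("a pure bending deformation decomposes as t * dkappa / 2", {
  # curvature drops at constant mid-line length, no noise: the generator's
  # kappa ratio with zero membrane strain is exactly a pure bending field
  sp <- synthetic_spec(mid_radius = 3, thickness = 0.6, arc_angle = 300,
                       kappa_ratio_inf = 0.9, tau_h = 1e-6,
                       membrane_strain_inf_pct = 0, noise_sd = 0, seed = 3)
  ring <- generate_sector_trace(sp, "ring")
  fin <- generate_sector_trace(sp, "cut_22h")
  g0 <- segment_geometry(ring$inner, ring$outer)
  g1 <- segment_geometry(fin$inner, fin$outer)
  e_in <- boundary_strain(g0$inner$length_mm, g1$inner$length_mm, "inner")
  e_out <- boundary_strain(g0$outer$length_mm, g1$outer$length_mm, "outer")
  d <- strain_decomposition(e_in, e_out)
  dkappa <- fin$truth$kappa_mid - ring$truth$kappa_mid
  expected_bending <- -sp$thickness * dkappa / 2 * 100
  expect_equal(d$bending_pct, expected_bending, tolerance = 0.05)
  expect_lt(abs(d$membrane_pct), 0.2)
})
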