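test_that("surface amplification matches the direct formula and known cases", {
  # hand-evaluated oracle: 1 - 10*pi*0.01 + 10*2*pi*0.1*1
  m <- microvillus_morphometry(length_um = 1, base_radius_um = 0.1,
                               tip_radius_um = 0.1, density_per_um2 = 10,
                               brush_border_extent_um = 1)
  expect_equal(surface_amplification(m), 1 - 0.1 * pi + 2 * pi, tolerance = 1e-12)
  expect_equal(round(surface_amplification(m), 3), 6.969)

  # choroid plexus morphometry gives about 12-fold
  amp <- surface_amplification(microvillus_morphometry())
  expect_equal(round(amp), 12)

  # flat membrane limit: density -> 0 is not constructible (positive-only),
  # but a vanishing density drives the factor to 1
  tiny <- microvillus_morphometry(density_per_um2 = 1e-12)
  expect_equal(surface_amplification(tiny), 1, tolerance = 1e-10)

  # hemispherical tip cap adds rho * 2 pi r_tip^2
  m2 <- microvillus_morphometry()
  expect_equal(surface_amplification(m2, tip_cap = TRUE) -
                 surface_amplification(m2),
               18 * 2 * pi * 0.12^2, tolerance = 1e-12)
})

test_that("surface amplification is monotone in density, radius and length", {
  base <- list(l = 1.71, r = 0.06, rho = 18)
  amp <- function(l, r, rho) {
    surface_amplification(microvillus_morphometry(
      length_um = l, base_radius_um = r, tip_radius_um = r + 0.06,
      density_per_um2 = rho, brush_border_extent_um = min(1.5, l)))
  }
  for (f in c(1.1, 1.5, 2)) {
    expect_gt(amp(base$l * f, base$r, base$rho), amp(base$l, base$r, base$rho))
    expect_gt(amp(base$l, base$r * f, base$rho), amp(base$l, base$r, base$rho))
    expect_gt(amp(base$l, base$r, base$rho * f), amp(base$l, base$r, base$rho))
  }
})

test_that("apparent area from wet weight reproduces the printed 4.6 cm^2", {
  expect_equal(apparent_area_from_mass(tissue_gross()), 4.6, tolerance = 1e-12)
  expect_equal(apparent_area_from_mass(tissue_gross(epithelium_mass_mg = 2.3)),
               2.3, tolerance = 1e-12)
  expect_error(tissue_gross(cell_height_um = 0), "positive")
})

test_that("true area combines apparent area and amplification", {
  amp <- surface_amplification(microvillus_morphometry())
  expect_equal(true_area(4.6, amp), 4.6 * amp)
  expect_equal(round(true_area(4.6, amp)), 57)
  expect_equal(true_area(4.6, 1), 4.6)
  expect_equal(true_area(2, 5), 10)
})

test_that("unit geometry matches hand arithmetic and its invariants", {
  g <- study_geometry()
  expect_equal(g$spacing_um, 1 / sqrt(18), tolerance = 1e-12)
  expect_equal(round(g$spacing_um, 4), 0.2357)
  expect_equal(round(g$void_area_um2, 4), 0.0442)
  expect_equal(round(g$channel_diameter_um, 4), 0.2374)
  expect_equal(g$n_units, 4.6 / (g$spacing_um^2 * 1e-8), tolerance = 1e-12)
  expect_equal(g$n_units, 8.3e9, tolerance = 0.01)

  # n_units * unit cell area recovers the apparent area exactly
  expect_equal(g$n_units * g$unit_cell_area_um2 * 1e-8, 4.6,
               tolerance = 1e-9)

  # wall area accounting: walls + base recover true - apparent + void base
  amp <- surface_amplification(microvillus_morphometry())
  total_wall_cm2 <- g$n_units * g$wall_area_um2 * 1e-8
  expected <- 4.6 * (amp - 1) + g$n_units * g$void_area_um2 * 1e-8
  expect_equal(total_wall_cm2, expected, tolerance = 0.01)
  # and is within a few percent of the true membrane area
  expect_equal(total_wall_cm2, true_area(4.6, amp), tolerance = 0.05)
})

test_that("vanishing microvillus radius gives the full-cell channel", {
  m <- microvillus_morphometry(base_radius_um = 1e-9, tip_radius_um = 1e-9)
  g <- derive_unit_geometry(m, 4.6)
  expect_equal(g$channel_diameter_um, 2 * g$spacing_um / sqrt(pi),
               tolerance = 1e-6)
})

test_that("overlapping microvilli are rejected", {
  m <- microvillus_morphometry(base_radius_um = 0.2, tip_radius_um = 0.2,
                               density_per_um2 = 18)
  expect_error(derive_unit_geometry(m, 4.6), "overlap")
})

test_that("equal-radius hydraulic equivalence is exposed as an option", {
  m <- microvillus_morphometry()
  g <- derive_unit_geometry(m, 4.6, hydraulic = "equal-radius")
  a_v <- g$void_area_um2
  expect_equal(g$channel_diameter_um, 2 * a_v / (pi * 0.06), tolerance = 1e-12)
})

test_that("dimensional round trips are identity", {
  x <- c(0.123, 4.56, 789)
  expect_equal(cm_to_um(um_to_cm(x)), x, tolerance = 1e-15)
  expect_equal(cm2_to_um2(um2_to_cm2(x)), x, tolerance = 1e-15)
  expect_equal(osmol_cm3_to_mosm(mosm_to_osmol_cm3(x)), x, tolerance = 1e-15)
  expect_equal(cm3_s_to_ul_min(ul_min_to_cm3_s(x)), x, tolerance = 1e-15)
})

test_that("invalid morphometry is rejected", {
  expect_error(microvillus_morphometry(length_um = -1), "positive")
  expect_error(microvillus_morphometry(tip_radius_um = 0.01), "tip_radius")
  expect_error(microvillus_morphometry(brush_border_extent_um = 2), "brush_border")
})
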