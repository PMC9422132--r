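test_that("Lp from slope and area matches hand unit conversion", {
  # 0.023 ul/min/mOsm over 4.6 cm^2 = 0.023/60 * 1e-3 * 1e3 / 4.6 cm/s/Osm
  expect_equal(lp_from_slope(0.023, 4.6), 0.023 / 60 / 4.6 * 1,
               tolerance = 1e-12)
  expect_equal(lp_from_slope(0.023, 4.6), 8.333e-5, tolerance = 1e-3)
  # within the documented input-rounding margin of the published 8.7e-5
  expect_equal(lp_from_slope(0.023, 4.6), 8.7e-5, tolerance = 0.05)
  # doubling linearity
  expect_equal(lp_from_slope(0.046, 4.6), 2 * lp_from_slope(0.023, 4.6))
  expect_error(lp_from_slope(0, 4.6), "positive")
})

test_that("series-membrane split doubles and recombines consistently", {
  expect_equal(split_series_membranes(8.7e-5), 1.74e-4)
  expect_equal(split_series_membranes(0), 0)
  # two equal membranes of 2x in series recombine to x
  x <- 8.7e-5
  each <- split_series_membranes(x)
  expect_equal(1 / (1 / each + 1 / each), x, tolerance = 1e-15)
})

test_that("per-true-area rescaling reproduces the luminal permeability", {
  amp <- surface_amplification(microvillus_morphometry())
  expect_equal(lp_per_true_area(1.74e-4, amp), 1.4e-5, tolerance = 0.01)
  expect_equal(lp_per_true_area(5e-5, 1), 5e-5)
  # order-of-magnitude cross-check quoted for the trans-epithelial value
  expect_equal(lp_per_true_area(8.7e-5, amp) / 7e-6, 1, tolerance = 0.01)
  expect_error(lp_per_true_area(1e-5, 0.5), ">= 1")
})

test_that("required gradient reproduces ~280 mOsm (~590 mOsm ventricular)", {
  r <- required_gradient(6.8, 4.6, 8.7e-5, plasma_osm_mosm = 307)
  expect_equal(r$delta_osm_req_mosm, 283, tolerance = 0.005)
  expect_equal(r$delta_osm_req_mosm, 280, tolerance = 0.02)
  expect_equal(r$ventricular_osm_mosm, 590, tolerance = 0.01)
  expect_equal(required_gradient(0, 4.6, 8.7e-5)$delta_osm_req_mosm, 0)
  # linear in Vp
  expect_equal(required_gradient(3.4, 4.6, 8.7e-5)$delta_osm_req_mosm,
               r$delta_osm_req_mosm / 2, tolerance = 1e-12)
})

test_that("isotonic ion-transfer rate reproduces 3.48e-5 mmol/s", {
  expect_equal(ion_transfer_rate(6.8, 307, 1.00), 3.48e-5, tolerance = 0.002)
  expect_equal(ion_transfer_rate(0, 307), 0)
  expect_equal(ion_transfer_rate(1, 300), 5.0e-6, tolerance = 1e-12)
})

test_that("van't Hoff pressure conversion matches hand arithmetic", {
  # 50 mol/m^3 * 8.314 * 310 / 133.322
  expect_equal(osmotic_pressure(50, 310), 50 * 8.314 * 310 / 133.322,
               tolerance = 1e-12)
  expect_equal(osmotic_pressure(50, 310), 967, tolerance = 0.001)
  expect_equal(osmotic_pressure(0), 0)
  # roughly ten-fold the mean arterial pressure range 67-97 mmHg
  ratio <- osmotic_pressure(50) / mean(c(67, 97))
  expect_gt(ratio, 5); expect_lt(ratio, 20)
})

test_that("chain identity: required gradient from fitted Lp equals vp/slope", {
  for (vp in c(1, 3.4, 6.8)) for (slope in c(0.01, 0.023, 0.05)) {
    for (area in c(2, 4.6, 10)) {
      lp <- lp_from_slope(slope, area)
      r <- required_gradient(vp, area, lp)
      expect_equal(r$delta_osm_req_mosm, vp / slope, tolerance = 1e-12)
    }
  }
})

test_that("operations scale with the homogeneity their formulas dictate", {
  for (k in c(0.5, 2, 10)) {
    expect_equal(lp_from_slope(0.023 * k, 4.6), k * lp_from_slope(0.023, 4.6))
    expect_equal(lp_from_slope(0.023, 4.6 * k), lp_from_slope(0.023, 4.6) / k)
    expect_equal(ion_transfer_rate(6.8 * k, 307), k * ion_transfer_rate(6.8, 307))
    expect_equal(required_gradient(6.8, 4.6, 8.7e-5 * k)$delta_osm_req_mosm,
                 required_gradient(6.8, 4.6, 8.7e-5)$delta_osm_req_mosm / k)
  }
})

test_that("the assembled chain carries every link consistently", {
  amp <- surface_amplification(microvillus_morphometry())
  ch <- permeability_chain(0.023, 4.6, amp, 6.8, plasma_osm_mosm = 306)
  expect_equal(ch$lp_membrane_cm_s_osm, 2 * ch$lp_trans_cm_s_osm)
  expect_equal(ch$lp_luminal_true_cm_s_osm,
               ch$lp_membrane_cm_s_osm / amp)
  expect_gt(ch$requirement$ventricular_osm_mosm, 306)
  # published-Lp override is honoured
  ch2 <- permeability_chain(0.023, 4.6, amp, 6.8, lp_trans_override = 8.7e-5)
  expect_equal(ch2$lp_trans_cm_s_osm, 8.7e-5)
  expect_equal(ch2$lp_luminal_true_cm_s_osm, 1.4e-5, tolerance = 0.01)
})
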