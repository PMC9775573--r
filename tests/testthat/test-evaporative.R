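test_that("vapour pressure matches psychrometric saturation and is well-behaved", {
  expect_equal(vapour_pressure(34, 0), 0)
  # saturation at 34 degC is ~5.32 kPa
  p100 <- vapour_pressure(34, 100)
  expect_equal(p100, 5322, tolerance = 0.01)
  expect_equal(vapour_pressure(34, 40), 0.40 * p100, tolerance = 1e-12)
  # strictly increasing in temperature, linear in RH
  temps <- seq(5, 40, by = 5)
  expect_true(all(diff(vapour_pressure(temps, 50)) > 0))
  rh <- seq(0, 100, by = 10)
  p <- vapour_pressure(30, rh)
  expect_equal(p, rh / 100 * vapour_pressure(30, 100), tolerance = 1e-12)
  expect_error(vapour_pressure(34, 150), "0, 100")
})

test_that("skin-temperature correction is the printed linear flux law", {
  expect_equal(corrected_skin_temperature(34, 0), 34)
  expect_equal(corrected_skin_temperature(34, 100), 32.68)
  expect_equal(round(corrected_skin_temperature(34, 372), 2), 29.09)
})

test_that("zone evaporative resistance is the pressure-gradient quotient", {
  expect_equal(zone_evap_resistance(5000, 2000, 0.1, 30), 10)
  expect_equal(zone_evap_resistance(5000, 2000, 0.1, 60), 5)  # halves
  expect_error(zone_evap_resistance(2000, 5000, 0.1, 30), "gradient")
})

test_that("whole-body reduction orders raw and corrected resistance", {
  geo <- default_geometry()
  # uniform flux 372 W/m2 at the 34 degC set-point, isothermal chamber
  st <- steady_from_means(rep(34, 17), 372 * geo$area, geo,
                          wet_env(), mode = "wet", skin_rh = 96)
  res <- whole_body_evap_resistance(st)
  expect_lt(res$ret, res$ret_raw)
  # direct evaluation of both forms
  p_a <- vapour_pressure(34, 40)
  p_s <- vapour_pressure(34, 96)
  p_sk <- vapour_pressure(34 - 0.0132 * 372, 96)
  expect_equal(res$ret_raw, (p_s - p_a) / 372, tolerance = 1e-12)
  expect_equal(res$ret, (p_sk - p_a) / 372, tolerance = 1e-12)
  expect_equal(res$heat_flux, 372, tolerance = 1e-12)
})

test_that("zero flux and isothermal violations are rejected", {
  geo <- tiny_geometry()
  st0 <- steady_from_means(c(34, 34), c(0, 0), geo, wet_env(),
                           mode = "wet", skin_rh = 96)
  expect_error(whole_body_evap_resistance(st0), "zero heat flux")
  st_warn <- steady_from_means(c(35, 35), c(20, 20), geo, wet_env(),
                               mode = "wet", skin_rh = 96)
  expect_warning(whole_body_evap_resistance(st_warn), "isothermal")
  st_fail <- steady_from_means(c(38, 38), c(20, 20), geo, wet_env(),
                               mode = "wet", skin_rh = 96)
  expect_error(whole_body_evap_resistance(st_fail), "isothermal")
})

test_that("the wet pipeline inverts a noise-free generated trial", {
  sp <- synthetic_spec(mode = "wet", true_zone_evap_resistance = 18.7,
                       noise_sd_temp = 0, noise_sd_flux_fraction = 0,
                       warmup_time_constant = 0, duration = 1200, seed = 1)
  res <- compute_evap(generate_trial(sp))
  expect_equal(res$ret, 18.7, tolerance = 1e-4)  # fixed-point tolerance
  expect_equal(unname(res$zone_ret), rep(18.7, 17), tolerance = 1e-4)
})

test_that("noisy wet trials recover the true resistance within a few percent", {
  sp <- synthetic_spec(mode = "wet", true_zone_evap_resistance = 18.7,
                       noise_sd_flux_fraction = 0.01, duration = 1800,
                       seed = 100)
  rec <- recovery_experiment(sp, n_seeds = 20, min_duration = 600)
  expect_true(all(abs(rec$relative_errors) < 0.02))
})

test_that("clothing evaporative resistance and indices reproduce the wardrobe", {
  expect_equal(round(clothing_evap_resistance(18.7, 8.0, 1.19), 1), 12.0)
  expect_equal(round(clothing_evap_resistance(41.8, 8.0, 1.32), 1), 35.7)
  expect_equal(clothing_evap_resistance(8.0, 8.0, 1.0), 0)  # bare skin
  expect_equal(round(permeability_index(0.187, 18.7), 2), 0.61)
  expect_equal(round(permeability_index(0.237, 29.3), 2), 0.49)
  expect_lt(permeability_index(0.187, 1e12), 1e-9)  # ret -> Inf limit

  wdb <- load_wardrobe()
  wet <- wdb$ensembles[!is.na(wdb$ensembles$ret), ]
  expect_equal(nrow(wet), 12L)
  rea <- wdb$reference$ensembles$ret[wdb$reference$ensembles$code == "SK"]
  recl <- clothing_evap_resistance(wet$ret, rea, wet$fcl)
  expect_lt(max(abs(recl - wet$recl)), 0.15)
  im <- permeability_index(wet$it, wet$ret)
  expect_lt(max(abs(im - wet$im)), 0.015)
  icl <- basic_insulation(wet$it, 0.099, wet$fcl)
  im_cl <- clothing_permeability_index(icl, recl)
  expect_lt(max(abs(im_cl - wet$im_cl)), 0.015)
})

test_that("permeability indices are invariant under area rescaling", {
  # scaling every area (hence every zone loss) leaves the whole-body
  # resistances, and so the indices, unchanged
  for (scale in c(0.5, 2)) {
    geo1 <- default_geometry()
    geo2 <- default_geometry(total_area = attr(geo1, "total_area") * scale)
    st1 <- steady_from_means(rep(34, 17), 300 * geo1$area, geo1, wet_env(),
                             mode = "wet", skin_rh = 96)
    st2 <- steady_from_means(rep(34, 17), 300 * geo2$area, geo2, wet_env(),
                             mode = "wet", skin_rh = 96)
    r1 <- whole_body_evap_resistance(st1)
    r2 <- whole_body_evap_resistance(st2)
    expect_equal(permeability_index(0.2, r1$ret),
                 permeability_index(0.2, r2$ret), tolerance = 1e-12)
  }
})
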