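test_that("the light field attenuates with depth, red faster than blue", {
  cfg0 <- generator_config(seed = 1, depth_m = 0)
  cfg7 <- generator_config(seed = 1, depth_m = 7)
  cfg15 <- generator_config(seed = 1, depth_m = 15)
  lf0 <- make_lightfield(cfg0)
  lf7 <- make_lightfield(cfg7)
  lf15 <- make_lightfield(cfg15)

  # at depth 0 the down-welling equals the (unattenuated) surface proxy
  expect_equal(max(lf0$down_welling$value), cfg0$surface_scale)
  expect_true(all(lf15$down_welling$value < lf7$down_welling$value))
  expect_true(all(lf7$down_welling$value < lf0$down_welling$value))

  red_blue <- function(lf) {
    integrate_spectrum(lf$down_welling, c(620, 700)) /
      integrate_spectrum(lf$down_welling, c(400, 480))
  }
  expect_lt(red_blue(lf7), red_blue(lf0))
  expect_lt(red_blue(lf15), red_blue(lf7))

  expect_true(all(lf7$side_welling_shaded$value <=
                    lf7$side_welling_exposed$value))
  expect_true(all(lf7$down_welling$value > 0))
})

test_that("zero component CV makes every individual equal to the means", {
  cfg <- generator_config(seed = 9, component_cv = 0)
  a <- make_individual(cfg, "ind1")
  b <- make_individual(cfg, "ind2")
  for (nm in c("sar_narrow", "sar_broad", "pet", "iris", "model_pupil")) {
    expect_identical(a[[nm]]$value, b[[nm]]$value)
    expect_equal(mean(a[[nm]]$value), unname(cfg$component_means[nm]),
                 tolerance = 1e-12)
  }
})

test_that("component scales are lognormal around the configured means", {
  cfg <- generator_config(seed = 42)
  m <- vapply(sprintf("ind%d", 1:1000), function(id)
    mean(make_individual(cfg, id)$sar_broad$value), numeric(1))
  se <- 0.06 * cfg$component_cv / sqrt(1000)
  expect_lt(abs(mean(m) - 0.06), 2 * se)
  expect_gt(sd(m), 0)
})

test_that("PET rises towards long wavelengths", {
  cfg <- generator_config(seed = 4)
  pet <- make_individual(cfg, "ind1")$pet
  expect_gt(pet$value[pet$wl == 700], pet$value[pet$wl == 380])
})

test_that("measurements are deterministic and exact when noise-free", {
  cfg <- generator_config(seed = 6)
  lf <- make_lightfield(cfg)
  comp <- make_individual(cfg, "ind1")

  m1 <- make_field_measurements(cfg, comp, lf)
  m2 <- make_field_measurements(cfg, comp, lf)
  expect_identical(lapply(m1, function(m) m$spectrum$value),
                   lapply(m2, function(m) m$spectrum$value))

  cfg0 <- generator_config(seed = 6, noise_cv = 0)
  m0 <- make_field_measurements(cfg0, comp, lf)
  p_ex <- find_measurement(m0, "pupil", "exposed", individual_id = "ind1")
  expect_identical(p_ex$spectrum$value,
                   predict_pupil_radiance(comp, lf, "exposed")$value)
  w_dn <- find_measurement(m0, "white_standard", "exposed",
                           "parallel_to_surface")
  expect_identical(w_dn$spectrum$value, lf$down_welling$value)

  # the full set: pupil (3 exposures incl. coaxial), iris x2, model pupil,
  # 3 field standards + 1 coaxial standard, 4 skin patches
  expect_length(m0, 14)
  expect_length(skin_reflectances(m0, "ind1"), 4)
})

test_that("dark-adaptation series follow the configured decay", {
  flat <- make_dark_adaptation_series(slope = 0, seed = 5)
  fit <- fit_dark_adaptation(flat, n_draws = 4000, seed = 6)
  ci <- fit$coefficients["time_min", ]
  expect_lte(ci$cri_low, 0); expect_gte(ci$cri_high, 0)

  # gamma_shape -> infinity approaches the deterministic mean curve
  big <- make_dark_adaptation_series(gamma_shape = 1e9, seed = 7)
  mu <- 27.3 * exp(-0.0099 * seq(0, 120, 10))
  expect_equal(big$total_reflectance[big$individual_id == "ind1"], mu,
               tolerance = 1e-3)
  exact <- make_dark_adaptation_series(gamma_shape = Inf, seed = 7)
  expect_equal(exact$total_reflectance[exact$individual_id == "ind1"], mu,
               tolerance = 1e-12)

  expect_error(make_dark_adaptation_series(slope = 0), "seed is required")
  expect_error(make_dark_adaptation_series(intercepts = -1, seed = 1),
               "positive")
})
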