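make_flat_components <- function(sar = 0.06, pet = 0.033, iris = 0.15,
                                 model = 8e-4, narrow = 12.01) {
  eyeshine_components(
    sar_narrow = flat_spct(narrow, kind = "reflectance"),
    sar_broad = flat_spct(sar, kind = "reflectance"),
    pet = flat_spct(pet, kind = "transmittance"),
    iris = flat_spct(iris, kind = "reflectance"),
    model_pupil = flat_spct(model, kind = "reflectance"))
}

make_flat_lightfield <- function(down = 200, side = 100, shade = 0.5,
                                 depth = 7) {
  lightfield(flat_spct(down), flat_spct(side), flat_spct(side * shade), depth)
}

test_that("pupil prediction combines the SAR and PET channels", {
  lf <- make_flat_lightfield()
  zero <- make_flat_components(sar = 0, pet = 0)
  expect_equal(predict_pupil_radiance(zero, lf, "exposed")$value, rep(0, 321))

  c06 <- make_flat_components(sar = 0.06, pet = 0)
  shaded <- predict_pupil_radiance(c06, lf, "shaded")
  expect_equal(shaded$value, rep(100 * 0.5 * 0.06, 321))
  expect_identical(shaded$kind, "photon_radiance")

  full <- make_flat_components()
  expect_equal(predict_pupil_radiance(full, lf, "exposed")$value,
               rep(100 * 0.06 + 200 * 0.033, 321))
})

test_that("pupil prediction is additive in channels and linear in light", {
  lf <- make_flat_lightfield()
  sar_only <- make_flat_components(pet = 0)
  pet_only <- make_flat_components(sar = 0)
  both <- make_flat_components()
  expect_equal(predict_pupil_radiance(both, lf, "exposed")$value,
               predict_pupil_radiance(sar_only, lf, "exposed")$value +
                 predict_pupil_radiance(pet_only, lf, "exposed")$value)

  lf2 <- make_flat_lightfield(down = 400, side = 200)
  expect_equal(predict_pupil_radiance(both, lf2, "exposed")$value,
               2 * predict_pupil_radiance(both, lf, "exposed")$value)
})

test_that("shaded prediction never exceeds the exposed prediction", {
  cfg <- generator_config(seed = 21)
  lf <- make_lightfield(cfg)
  comp <- make_individual(cfg, "ind1")
  expect_true(all(predict_pupil_radiance(comp, lf, "shaded")$value <=
                    predict_pupil_radiance(comp, lf, "exposed")$value))
  expect_true(all(predict_iris_radiance(comp, lf, "shaded")$value <=
                    predict_iris_radiance(comp, lf, "exposed")$value))
})

test_that("iris prediction is the lit-surface product", {
  lf <- make_flat_lightfield()
  comp <- make_flat_components(iris = 0.15)
  expect_equal(predict_iris_radiance(comp, lf, "exposed")$value, rep(15, 321))
  dark <- make_flat_components(iris = 0)
  expect_equal(predict_iris_radiance(dark, lf, "shaded")$value, rep(0, 321))
})

test_that("log-ratio match scores identity as 1 and obeys the log law", {
  m <- smooth_spct(30, base = 1e16)
  expect_identical(log_ratio_match(m, m), 1)

  sq <- spct(m$wl, m$value^2)          # all values far above 1
  expect_equal(log_ratio_match(sq, m), 2, tolerance = 1e-12)

  near_one <- flat_spct(1.0005)
  expect_error(log_ratio_match(m, near_one), "undefined")
})

test_that("1% measurement noise moves the match only slightly", {
  matches <- vapply(1:20, function(seed) {
    cfg <- generator_config(seed = seed, noise_cv = 0.01)
    lf <- make_lightfield(cfg)
    truth <- make_individual(cfg, "ind1")
    ms <- make_field_measurements(cfg, truth, lf)
    hat <- decompose_individual(ms, "ind1")
    log_ratio_match(predict_pupil_radiance(hat, lf, "exposed"),
                    find_measurement(ms, "pupil", "exposed",
                                     individual_id = "ind1"))
  }, numeric(1))
  expect_true(all(abs(matches - 1) < 0.05))
})

test_that("noise-free generate-decompose-predict closes exactly", {
  for (depth in c(7, 15)) {
    cfg <- generator_config(seed = 33, noise_cv = 0, depth_m = depth)
    lf <- make_lightfield(cfg)
    truth <- make_individual(cfg, "ind2")
    ms <- make_field_measurements(cfg, truth, lf)
    hat <- decompose_individual(ms, "ind2")
    for (expo in c("exposed", "shaded")) {
      expect_equal(
        log_ratio_match(predict_pupil_radiance(hat, lf, expo),
                        find_measurement(ms, "pupil", expo,
                                         individual_id = "ind2")),
        1, tolerance = 1e-12)
      expect_equal(
        log_ratio_match(predict_iris_radiance(hat, lf, expo),
                        find_measurement(ms, "iris", expo,
                                         individual_id = "ind2")),
        1, tolerance = 1e-12)
    }
  }
})

test_that("light fields flag shading that adds light", {
  expect_warning(
    lightfield(flat_spct(10), flat_spct(5), flat_spct(6), 7),
    "shaded side-welling exceeds")
  expect_error(lightfield(flat_spct(10), flat_spct(5),
                          set_kind(flat_spct(1), "reflectance"), 7),
               "photon_radiance")
})
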