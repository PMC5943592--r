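test_that("wavelength grids validate and enumerate correctly", {
  g <- canonical_grid()
  expect_length(wavelengths(g), 321)
  expect_equal(wavelengths(wl_grid(400, 410, 5)), c(400, 405, 410))
  expect_error(wl_grid(700, 380), "start_nm")
  expect_error(wl_grid(380, 700, 0), "step_nm")
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(spct(1:10, 1:9), "lengths differ")
  expect_error(spct(c(380, 381), c(1, NA)), "non-finite")
  expect_error(spct(c(381, 380, 382), c(1, 1, 1)), "strictly increasing")
  s <- spct(380:700, rep(2, 321), "reflectance")
  expect_s3_class(s, "spct")
  expect_identical(s$kind, "reflectance")
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  sub <- wl_grid(400, 600, 1)
  const <- flat_spct(3.5)
  expect_equal(resample(const, sub)$value, rep(3.5, 201))

  line <- spct(seq(380, 700, 5), seq(380, 700, 5))
  fine <- resample(line, canonical_grid())
  expect_equal(fine$value, 380:700)

  r <- smooth_spct(1)
  expect_equal(resample(r, canonical_grid())$value, r$value)
  expect_identical(resample(r, canonical_grid())$kind, r$kind)

  expect_error(resample(spct(400:500, rep(1, 101)), canonical_grid()),
               "beyond source range")
})

test_that("integration matches closed forms and a Riemann-sum oracle", {
  expect_equal(integrate_spectrum(flat_spct(1)), 320)
  expect_equal(integrate_spectrum(flat_spct(0)), 0)

  # triangle peaking mid-window
  wl <- 380:700
  tri <- spct(wl, pmax(0, 1 - abs(wl - 540) / 100))
  oracle <- riemann_tab(wl, tri$value)
  expect_equal(integrate_spectrum(tri), oracle, tolerance = 1e-6)

  # sub-window integration, window edges between samples
  expect_equal(integrate_spectrum(flat_spct(2), c(400.5, 500.5)), 200)
  expect_error(integrate_spectrum(tri, c(500, 500)), "empty window")
  expect_error(integrate_spectrum(tri, c(300, 500)), "outside")
})

test_that("integration is linear in its argument", {
  for (seed in 1:5) {
    s1 <- smooth_spct(seed)
    s2 <- smooth_spct(seed + 100)
    lhs <- integrate_spectrum(2.5 * s1 + 0.7 * s2)
    rhs <- 2.5 * integrate_spectrum(s1) + 0.7 * integrate_spectrum(s2)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("white-standard normalisation gives exact ratios", {
  std <- smooth_spct(2, base = 10)
  expect_equal(normalize_to_standard(std, std)$value, rep(1, 321))
  tgt <- set_kind(std * 0.06, "photon_radiance")
  r <- normalize_to_standard(tgt, std)
  expect_equal(r$value, rep(0.06, 321))
  expect_identical(r$kind, "reflectance")

  # coaxial retroreflection: ratios above 1 are legitimate
  retro <- normalize_to_standard(set_kind(std * 12, "photon_radiance"), std)
  expect_true(all(retro$value > 1))

  bad <- spct(380:700, rep(0, 321))
  expect_error(normalize_to_standard(std, bad), "must be > 0")
  expect_error(normalize_to_standard(set_kind(std, "reflectance"), std),
               "photon_radiance")
})

test_that("total reflectance is the ratio of integrated radiances", {
  std <- smooth_spct(3, base = 5)
  expect_equal(total_reflectance(std, std), 1)
  expect_equal(total_reflectance(set_kind(std * 27.3, "photon_radiance"), std),
               27.3, tolerance = 1e-12)

  # wavelength-varying ratio: must equal ratio of Riemann integrals, which
  # differs from integrating the spectral ratio
  pupil <- smooth_spct(4, base = 2)
  oracle <- riemann_tab(pupil$wl, pupil$value) / riemann_tab(std$wl, std$value)
  expect_equal(total_reflectance(pupil, std), oracle, tolerance = 1e-6)

  expect_error(total_reflectance(std, flat_spct(0)), "must be > 0")
})

test_that("spectral arithmetic demands a shared grid", {
  a <- flat_spct(1)
  b <- flat_spct(1, wl_grid(380, 699, 1))
  expect_error(a + b, "different wavelength grids")
  expect_equal((a * 2 + a)$value, rep(3, 321))
})

test_that("CSV round trip is bit-identical and parsing enforces the format", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  cfg <- generator_config(seed = 11)
  comp <- make_individual(cfg, "ind1")
  ms <- make_field_measurements(cfg, comp, make_lightfield(cfg))
  write_spectra(ms, tmp)
  back <- read_spectra(tmp)
  expect_setequal(names(back), names(ms))
  for (k in names(ms)) {
    expect_identical(back[[k]]$spectrum$value, ms[[k]]$spectrum$value)
    expect_identical(back[[k]]$target, ms[[k]]$target)
    expect_identical(back[[k]]$exposure, ms[[k]]$exposure)
  }

  # minimal two-row file, one group
  writeLines(c("wavelength_nm,value,individual_id,target,exposure",
               "500,1.5,f1,pupil,exposed",
               "400,2.5,f1,pupil,exposed"), tmp)
  one <- read_spectra(tmp)
  expect_length(one, 1)
  expect_equal(one[[1]]$spectrum$wl, c(400, 500))      # sorted ascending
  expect_equal(one[[1]]$spectrum$value, c(2.5, 1.5))

  writeLines(c("wavelength_nm,value,individual_id,target,exposure",
               "400,1,f1,pupil,exposed",
               "400,2,f1,pupil,exposed"), tmp)
  expect_error(read_spectra(tmp), "duplicate wavelengths")

  writeLines(c("wavelength_nm,value", "400,1"), tmp)
  expect_error(read_spectra(tmp), "missing required columns")

  writeLines(c("wavelength_nm,value,individual_id,target,exposure",
               "400,-1,f1,pupil,exposed",
               "500,2,f1,pupil,exposed"), tmp)
  expect_warning(neg <- read_spectra(tmp), "clamped 1 negative")
  expect_equal(neg[[1]]$spectrum$value, c(0, 2))
})

test_that("white standards must declare an orientation", {
  s <- flat_spct(1)
  expect_error(measurement(s, "white_standard", "exposed"),
               "standard_orientation")
  ok <- measurement(s, "white_standard", "exposed", "parallel_to_surface")
  expect_s3_class(ok, "spct_meas")
})
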