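vs <- triplefin_visual_system()

test_that("pigment template is peak-normalised, unimodal and well-shaped", {
  for (lmax in c(468, 517, 530)) {
    s <- pigment_template(lmax)
    expect_equal(max(s$value), 1)
    expect_equal(s$wl[which.max(s$value)], lmax)
    # unimodal: the sign of the derivative changes exactly once
    d <- diff(s$value)
    expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)
  }
  expect_error(pigment_template(300), "350")
  expect_error(pigment_template(700), "350")
})

test_that("template half-max bandwidth matches a dense scan of the formula", {
  for (lmax in c(450, 517, 560)) {
    s <- pigment_template(lmax)
    # package route: half-max crossings interpolated from the 1-nm curve
    above <- s$value >= 0.5
    lo_i <- which(above)[1]
    hi_i <- rev(which(above))[1]
    interp_cross <- function(i0, i1) {
      stats::approx(s$value[c(i0, i1)], s$wl[c(i0, i1)], xout = 0.5)$y
    }
    width_pkg <- interp_cross(hi_i, hi_i + 1) - interp_cross(lo_i, lo_i - 1)

    # oracle: brute-force scan of an independent copy of the closed form
    wl_fine <- seq(380, 700, by = 0.001)
    v <- a1_template_fun(wl_fine, lmax)
    v <- v / max(v)
    width_oracle <- diff(range(wl_fine[v >= 0.5]))
    expect_equal(width_pkg, width_oracle, tolerance = 1e-3)
  }
})

test_that("quantum catch integrates radiance x sensitivity x media", {
  expect_equal(quantum_catch(flat_spct(0), vs, "mws"), 0)

  # rectangular sensitivity on its own grid gives the rectangle area
  g <- wl_grid(500, 600, 1)
  rect_vs <- visual_system(
    lambda_max = c(sws = 520, mws = 550, lws = 580),
    sensitivities = list(sws = flat_spct(1, g, "sensitivity"),
                         mws = flat_spct(1, g, "sensitivity"),
                         lws = flat_spct(1, g, "sensitivity")),
    grid = g)
  expect_equal(quantum_catch(flat_spct(1, g), rect_vs, "mws"), 100)

  # arbitrary smooth spectra against the fine-grid Riemann oracle
  r <- smooth_spct(40, base = 1e15)
  for (rec in c("sws", "mws", "lws")) {
    sens <- vs$receptors[[rec]]$sensitivity
    oracle <- riemann_tab(r$wl, r$value * sens$value)
    expect_equal(quantum_catch(r, vs, rec), oracle, tolerance = 1e-6)
  }
  expect_error(quantum_catch(r, vs, "uvs"), "unknown receptor")
})

test_that("ocular media attenuate the catch", {
  vs_om <- visual_system(ocular_media = ocular_media_logistic())
  r <- flat_spct(1)
  expect_lt(quantum_catch(r, vs_om, "sws"), quantum_catch(r, vs, "sws"))
  om <- ocular_media_logistic()
  expect_true(all(om$value >= 0 & om$value <= 1))
  expect_lt(om$value[om$wl == 390], om$value[om$wl == 600])
})

test_that("chromatic JND has the receptor-noise metric properties", {
  expect_equal(chromatic_jnd(c(1, 2, 3), c(1, 2, 3), vs), 0)
  # uniform brightness change cancels
  expect_equal(chromatic_jnd(c(1, 2, 3), 2 * c(1, 2, 3), vs), 0,
               tolerance = 1e-12)
  # hand-evaluated value for a unit log shift in the LWS channel
  expect_equal(chromatic_jnd(c(1, 1, 1), c(1, 1, exp(1)), vs), 14.907,
               tolerance = 1e-3)
  # symmetry and scale invariance
  qa <- c(0.3, 1.1, 0.7); qb <- c(0.5, 0.9, 1.4)
  expect_equal(chromatic_jnd(qa, qb, vs), chromatic_jnd(qb, qa, vs))
  expect_equal(chromatic_jnd(qa * 13, qb * 13, vs),
               chromatic_jnd(qa, qb, vs), tolerance = 1e-12)
  expect_error(chromatic_jnd(c(0, 1, 1), c(1, 1, 1), vs),
               "strictly positive")
})

test_that("general JND solution matches the trichromat closed form", {
  set.seed(77)
  for (k in 1:1000) {
    qa <- exp(runif(3, -2, 2)); qb <- exp(runif(3, -2, 2))
    expect_equal(chromatic_jnd(qa, qb, vs), jnd_closed_form(qa, qb),
                 tolerance = 1e-9)
  }
})

test_that("Michelson contrast spectrum is signed, bounded and zero iff equal", {
  a <- smooth_spct(50)
  expect_equal(michelson_spectrum(a, a)$value, rep(0, 321))
  expect_equal(michelson_spectrum(3 * a, a)$value, rep(0.5, 321))
  for (seed in 1:10) {
    x <- smooth_spct(seed); y <- smooth_spct(seed + 500)
    cm <- michelson_spectrum(x, y)$value
    expect_true(all(cm >= -1 & cm <= 1))
    expect_true(all((cm == 0) == (x$value == y$value)))
  }
  z <- flat_spct(0)
  expect_error(michelson_spectrum(z, z), "undefined")
})

test_that("achromatic contrast uses the summed double-cone catches", {
  a <- smooth_spct(60, base = 1e15)
  expect_equal(achromatic_contrast(a, a, vs), 0)
  # luminance catches in ratio 3:1 give (3-1)/(3+1)
  expect_equal(achromatic_contrast(flat_spct(3), flat_spct(1), vs), 0.5,
               tolerance = 1e-12)
  # dark model pupil against the iris under a common illuminant
  ill <- flat_spct(100)
  cm <- achromatic_contrast(set_kind(ill * 8e-4, "photon_radiance"),
                            set_kind(ill * 0.15, "photon_radiance"), vs)
  expect_equal(round(cm, 2), 0.99)
  # invariant to common scaling of both radiances
  expect_equal(achromatic_contrast(a * 5, smooth_spct(61, base = 1e15) * 5, vs),
               achromatic_contrast(a, smooth_spct(61, base = 1e15), vs),
               tolerance = 1e-10)
  expect_error(achromatic_contrast(flat_spct(0), flat_spct(0), vs),
               "undefined")
})

test_that("scenarios assemble contrasts and keep the model column constant", {
  cfg <- generator_config(seed = 2)
  lf <- make_lightfield(cfg)
  comp <- make_individual(cfg, "ind1")
  scen <- default_scenarios(cfg$shade_fraction)

  res <- lapply(scen, function(sc) run_scenario(comp, lf, sc, vs))
  model_cm <- vapply(res, function(r) r$model$achromatic_michelson, numeric(1))
  # model pupil and iris both scale with side-welling only
  expect_equal(max(model_cm) - min(model_cm), 0, tolerance = 1e-10)
  model_jnd <- vapply(res, function(r) r$model$chromatic_jnd, numeric(1))
  expect_equal(max(model_jnd) - min(model_jnd), 0, tolerance = 1e-8)

  nat_cm <- vapply(res, function(r) r$natural$achromatic_michelson, numeric(1))
  expect_true(all(nat_cm < model_cm))

  expect_error(scenario_spec("bad", 1.2, 1), "\\[0, 1\\]")
  dark_lf <- lightfield(flat_spct(0), flat_spct(0), flat_spct(0), 7)
  expect_error(run_scenario(comp, dark_lf, scen$s1, vs), "zero")
})

test_that("skin-patch contrasts enumerate unordered pairs", {
  cfg <- generator_config(seed = 2)
  lf <- make_lightfield(cfg)
  same <- replicate(3, flat_spct(0.2, kind = "reflectance"),
                    simplify = FALSE)
  expect_equal(skin_patch_contrasts(same, lf, vs), rep(0, 3))
  five <- lapply(seq(0.1, 0.5, 0.1), flat_spct, kind = "reflectance")
  expect_length(skin_patch_contrasts(five, lf, vs), 10)
  expect_error(skin_patch_contrasts(five[1], lf, vs), "at least 2")
})
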