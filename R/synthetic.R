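#' Configuration of the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: a coastal
#' underwater light field at the study depths (7 and 15 m), white-standard
#' radiances, per-individual eyeshine component spectra consistent with
#' the measured laboratory means (broad SAR 0.06, PET 0.033 with a
#' long-wavelength rise, iris 0.15, model pupil 0.0008, narrow SAR 12.01),
#' field-style measurement sets with multiplicative lognormal noise, and
#' dark-adaptation reflectance decay series.
#'
#' @param depth_m Depth in metres (default 7).
#' @param kd_base Diffuse attenuation floor in m^-1 (default 0.12,
#'   Jerlov-like coastal water).
#' @param kd_red_slope Additional attenuation per nm above 550 nm, in
#'   m^-1 nm^-1 (default 0.004), producing the loss of red light with
#'   depth.
#' @param side_fraction Side-welling radiance as a fraction of
#'   down-welling (default 0.28).
#' @param shade_fraction Fraction of side-welling light remaining under a
#'   shade (default 0.55).
#' @param component_means Named means of the component scale factors:
#'   `sar_broad`, `pet`, `iris`, `model_pupil`, `sar_narrow`.
#' @param component_cv Between-individual coefficient of variation of the
#'   component scales (lognormal; default 0.15).
#' @param pet_longwave_slope Strength of the linear long-wavelength tilt of
#'   the PET transmittance spectrum (> 0; default 0.6, giving a 4-fold
#'   rise from 380 to 700 nm around an unchanged spectral mean).
#' @param noise_cv Multiplicative lognormal measurement noise CV applied
#'   independently per wavelength channel (default 0.01, instrument
#'   repeatability).
#' @param n_individuals Number of fish (default 3, as measured in the
#'   field).
#' @param seed Integer seed; required. All generator randomness is
#'   Mersenne-Twister, fully determined by this seed.
#' @param skin_means Mean reflectances of the four skin patches around the
#'   iris; the first two share a mean (paired patches of the same skin
#'   type), so pairwise patch contrasts span about 0--0.6.
#' @param surface_scale Peak surface radiance in photons s-1 m-2 sr-1 nm-1
#'   (default 5e17, bright daylight).
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(depth_m = 7,
                             kd_base = 0.12,
                             kd_red_slope = 0.004,
                             side_fraction = 0.28,
                             shade_fraction = 0.55,
                             component_means = c(sar_broad = 0.06,
                                                 pet = 0.033,
                                                 iris = 0.15,
                                                 model_pupil = 0.0008,
                                                 sar_narrow = 12.01),
                             component_cv = 0.15,
                             pet_longwave_slope = 0.6,
                             noise_cv = 0.01,
                             n_individuals = 3,
                             seed,
                             skin_means = c(0.07, 0.07, 0.15, 0.30),
                             surface_scale = 5e17) {
  if (missing(seed)) stop("generator_config: seed is required")
  if (side_fraction <= 0 || side_fraction > 1)
    stop("generator_config: side_fraction must be in (0, 1]")
  if (shade_fraction <= 0 || shade_fraction >= 1)
    stop("generator_config: shade_fraction must be in (0, 1)")
  need <- c("sar_broad", "pet", "iris", "model_pupil", "sar_narrow")
  if (!all(need %in% names(component_means)) || any(component_means <= 0))
    stop("generator_config: component_means must name positive ",
         paste(need, collapse = ", "))
  if (pet_longwave_slope <= 0 || pet_longwave_slope >= 1)
    stop("generator_config: pet_longwave_slope must be in (0, 1)")
  if (component_cv < 0 || noise_cv < 0)
    stop("generator_config: CVs must be non-negative")
  structure(list(depth_m = depth_m, kd_base = kd_base,
                 kd_red_slope = kd_red_slope, side_fraction = side_fraction,
                 shade_fraction = shade_fraction,
                 component_means = component_means,
                 component_cv = component_cv,
                 pet_longwave_slope = pet_longwave_slope,
                 noise_cv = noise_cv, n_individuals = n_individuals,
                 seed = as.integer(seed), skin_means = skin_means,
                 surface_scale = surface_scale),
            class = "generator_config")
}

# smooth 5800-K Planck surface-daylight proxy, photon radiance, peak scaled
.surface_proxy <- function(grid = canonical_grid(), scale = 5e17,
                           temp_k = 5800) {
  wl <- wavelengths(grid)
  v <- wl^-4 / expm1(1.43877688e7 / (wl * temp_k))  # hc/k in nm K
  spct(wl, scale * v / max(v), "photon_radiance")
}

.kd <- function(wl, cfg) cfg$kd_base + cfg$kd_red_slope * pmax(0, wl - 550)

# component spectral shapes, normalised to mean 1 on the canonical grid
.component_shape <- function(name, cfg, grid = canonical_grid()) {
  wl <- wavelengths(grid)
  v <- switch(name,
    sar_broad = 1 + 0.10 * exp(-((wl - 480) / 90)^2),
    pet = 1 + cfg$pet_longwave_slope * (wl - 540) / 160,
    iris = 1 + 0.20 * (wl - 540) / 160,
    model_pupil = rep(1, length(wl)),
    sar_narrow = 1 + 0.15 * exp(-((wl - 560) / 80)^2),
    stop("unknown component ", name))
  v / mean(v)
}

# order-sensitive polynomial hash so ind12 and ind21 get distinct draws
.id_hash <- function(id) {
  h <- 0
  for (k in utf8ToInt(id)) h <- (h * 131 + k) %% 1000003
  as.integer(h)
}

#' Simulate an underwater light field
#'
#' Down-welling radiance is a smooth 5800-K Planck daylight proxy
#' attenuated as `exp(-Kd(lambda) * depth)` with
#' `Kd = kd_base + kd_red_slope * max(0, lambda - 550)` per metre, so red
#' light disappears faster with depth as in coastal water. Side-welling
#' light is `side_fraction` of down-welling; its shaded variant is
#' `shade_fraction` of the exposed one. All three are strictly positive.
#'
#' @param cfg A [generator_config()].
#' @return A [lightfield()] at `cfg$depth_m`.
#' @export
make_lightfield <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  grid <- canonical_grid()
  wl <- wavelengths(grid)
  surf <- .surface_proxy(grid, cfg$surface_scale)
  down <- spct(wl, surf$value * exp(-.kd(wl, cfg) * cfg$depth_m),
               "photon_radiance")
  side_ex <- down * cfg$side_fraction
  side_sh <- side_ex * cfg$shade_fraction
  lightfield(down, side_ex, side_sh, depth_m = cfg$depth_m)
}

#' Simulate one individual's eyeshine component spectra
#'
#' Component scale factors are drawn from lognormal distributions with the
#' configured means and CV (so the population mean of each component equals
#' its configured mean); spectral shapes are smooth fixed curves with mean
#' 1, including the linear long-wavelength rise of PET. With
#' `component_cv = 0` every individual equals the configured means.
#'
#' @param cfg A [generator_config()].
#' @param individual_id Identifier; also seeds this individual's draws, so
#'   the same (seed, id) pair always yields the same fish.
#' @return An [eyeshine_components()] object.
#' @export
make_individual <- function(cfg, individual_id = "ind1") {
  stopifnot(inherits(cfg, "generator_config"))
  grid <- canonical_grid()
  s <- sqrt(log(1 + cfg$component_cv^2))
  nm <- c("sar_broad", "pet", "iris", "model_pupil", "sar_narrow")
  scales <- with_seed(
    stage_seed(cfg$seed, "individuals", .id_hash(individual_id)),
    stats::rlnorm(length(nm), meanlog = log(cfg$component_means[nm]) - s^2 / 2,
                  sdlog = s))
  names(scales) <- nm
  comp <- function(name, kind)
    spct(wavelengths(grid), scales[[name]] * .component_shape(name, cfg, grid),
         kind)
  eyeshine_components(
    sar_narrow = comp("sar_narrow", "reflectance"),
    sar_broad = comp("sar_broad", "reflectance"),
    pet = comp("pet", "transmittance"),
    iris = comp("iris", "reflectance"),
    model_pupil = comp("model_pupil", "reflectance"),
    individual_id = individual_id)
}

#' Simulate a field-style measurement set for one individual
#'
#' Applies the forward optics of [predict_pupil_radiance()] and
#' [predict_iris_radiance()] to the individual's components and the light
#' field, then multiplies every wavelength channel of each measurement by
#' an independent lognormal noise factor of CV `noise_cv` (mean 1,
#' emulating detector channel noise). The set contains the exposed
#' and shaded pupil, exposed and shaded iris, four skin patches, the model
#' pupil, three field white standards (down-welling, side-welling exposed,
#' side-welling shaded), and the coaxial pupil/standard pair used for
#' narrow-sense SAR. Skin patches are labelled
#' `"<individual>:skin<k>"`. With `noise_cv = 0` the measurements equal
#' the noise-free forward model exactly; the same seed always produces
#' bit-identical output.
#'
#' @param cfg A [generator_config()].
#' @param components An [eyeshine_components()] object.
#' @param lf A [lightfield()].
#' @return A named list of [measurement()]s.
#' @export
make_field_measurements <- function(cfg, components, lf) {
  stopifnot(inherits(cfg, "generator_config"),
            inherits(components, "eyeshine_components"),
            inherits(lf, "lightfield"))
  id <- components$individual_id
  grid <- canonical_grid()
  s <- sqrt(log(1 + cfg$noise_cv^2))
  coax_source <- .surface_proxy(grid, scale = 1e16, temp_k = 8000)

  clean <- list(
    list(spct = lf$down_welling, target = "white_standard",
         exposure = "exposed", orient = "parallel_to_surface", mid = id),
    list(spct = lf$side_welling_exposed, target = "white_standard",
         exposure = "exposed", orient = "facing_instrument", mid = id),
    list(spct = lf$side_welling_shaded, target = "white_standard",
         exposure = "shaded", orient = "facing_instrument", mid = id),
    list(spct = predict_pupil_radiance(components, lf, "exposed"),
         target = "pupil", exposure = "exposed", orient = "none", mid = id),
    list(spct = predict_pupil_radiance(components, lf, "shaded"),
         target = "pupil", exposure = "shaded", orient = "none", mid = id),
    list(spct = predict_iris_radiance(components, lf, "exposed"),
         target = "iris", exposure = "exposed", orient = "none", mid = id),
    list(spct = predict_iris_radiance(components, lf, "shaded"),
         target = "iris", exposure = "shaded", orient = "none", mid = id),
    list(spct = set_kind(lf$side_welling_exposed * components$model_pupil,
                         "photon_radiance"),
         target = "model_pupil", exposure = "exposed", orient = "none",
         mid = id),
    list(spct = coax_source, target = "white_standard", exposure = "coaxial",
         orient = "facing_instrument", mid = id),
    list(spct = set_kind(coax_source * components$sar_narrow,
                         "photon_radiance"),
         target = "pupil", exposure = "coaxial", orient = "none", mid = id))
  for (k in seq_along(cfg$skin_means)) {
    clean[[length(clean) + 1L]] <- list(
      spct = set_kind(lf$side_welling_exposed * cfg$skin_means[k],
                      "photon_radiance"),
      target = "skin", exposure = "exposed", orient = "none",
      mid = sprintf("%s:skin%d", id, k))
  }

  n_wl <- length(wavelengths(grid))
  noise <- with_seed(
    stage_seed(cfg$seed, "measurements", .id_hash(id)),
    matrix(stats::rlnorm(length(clean) * n_wl, meanlog = -s^2 / 2,
                         sdlog = s),
           nrow = length(clean), byrow = TRUE))
  if (cfg$noise_cv == 0) noise[] <- 1

  out <- Map(function(entry, k) {
    measurement(entry$spct * noise[k, ], target = entry$target,
                exposure = entry$exposure,
                standard_orientation = entry$orient,
                depth_m = lf$depth_m, individual_id = entry$mid)
  }, clean, seq_along(clean))
  names(out) <- vapply(out, .meas_key, character(1))
  out
}

#' Extract skin-patch reflectances from a measurement set
#'
#' Normalises each skin-patch radiance of one individual by the exposed
#' side-welling white standard of the same set.
#'
#' @param measurements A measurement list from [make_field_measurements()]
#'   or [read_spectra()].
#' @param individual_id The fish whose patches to extract.
#' @return A list of reflectance [spct()]s, one per patch.
#' @export
skin_reflectances <- function(measurements, individual_id) {
  white <- find_measurement(measurements, "white_standard", "exposed",
                            "facing_instrument")
  hit <- vapply(measurements, function(m)
    m$target == "skin" &&
      startsWith(m$individual_id, paste0(individual_id, ":")),
    logical(1))
  if (!any(hit)) stop("skin_reflectances: no skin patches for ", individual_id)
  lapply(measurements[hit], surface_reflectance, white_facing = white)
}

#' Simulate dark-adaptation reflectance decay series
#'
#' One series per individual: total reflectance drawn from a gamma
#' distribution with mean `intercept_i * exp(slope * t)` and the given
#' shape, on a regular time grid. `gamma_shape = Inf` gives the
#' deterministic mean curve. Defaults reproduce the laboratory protocol:
#' 3 fish measured every 10 min for 2 h, starting near 27-times-white
#' reflectance (one brighter fish near 35) and decaying about 1% per
#' minute.
#'
#' @param n_individuals Number of fish (default 3).
#' @param duration_min Length of the series in minutes (default 120).
#' @param step_min Sampling step in minutes (default 10, giving 13 points).
#' @param intercepts Starting total reflectance per individual (recycled).
#' @param slope Log-link slope per minute (default -0.0099, a 1% decay per
#'   minute).
#' @param gamma_shape Gamma shape parameter (default 30, about 18%
#'   observation CV).
#' @param seed Integer seed; required.
#' @return Data frame with columns `time_min`, `total_reflectance`,
#'   `individual_id`.
#' @export
make_dark_adaptation_series <- function(n_individuals = 3,
                                        duration_min = 120,
                                        step_min = 10,
                                        intercepts = c(27.3, 24, 35),
                                        slope = -0.0099,
                                        gamma_shape = 30,
                                        seed) {
  if (missing(seed)) stop("make_dark_adaptation_series: seed is required")
  if (any(intercepts <= 0)) stop("intercepts must be positive")
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  times <- seq(0, duration_min, by = step_min)
  intercepts <- rep_len(intercepts, n_individuals)
  draw <- function() {
    do.call(rbind, lapply(seq_len(n_individuals), function(i) {
      mu <- intercepts[i] * exp(slope * times)
      y <- if (is.infinite(gamma_shape)) mu
           else stats::rgamma(length(mu), shape = gamma_shape,
                              rate = gamma_shape / mu)
      data.frame(time_min = times, total_reflectance = y,
                 individual_id = sprintf("ind%d", i))
    }))
  }
  with_seed(seed, draw())
}
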