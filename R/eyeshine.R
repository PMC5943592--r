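#' Eyeshine component spectra of one individual
#'
#' Bundles the decomposed eyeshine and surface spectra of one fish:
#' narrow-sense SAR reflectance (the retroreflective component measured
#' under coaxial illumination, routinely far above 1), broad-sense SAR
#' reflectance (reflection of the general side-welling field by the stratum
#' argenteum), PET transmittance (down-welling light transmitted through
#' the dorsal eye wall and pigment epithelium, leaving via the pupil),
#' iris reflectance and the black model-pupil reflectance. All spectra must
#' live on the canonical 380--700 nm grid. Broad SAR, PET, iris and model
#' pupil are constrained to [0, 2]; narrow SAR is unbounded above.
#'
#' @param sar_narrow Reflectance [spct()] (coaxial geometry).
#' @param sar_broad Reflectance [spct()].
#' @param pet Transmittance [spct()].
#' @param iris Reflectance [spct()].
#' @param model_pupil Reflectance [spct()].
#' @param individual_id Identifier.
#' @return An object of class `"eyeshine_components"`.
#' @export
eyeshine_components <- function(sar_narrow, sar_broad, pet, iris, model_pupil,
                                individual_id = "ind1") {
  comps <- list(sar_narrow = sar_narrow, sar_broad = sar_broad, pet = pet,
                iris = iris, model_pupil = model_pupil)
  wl_ref <- wavelengths(canonical_grid())
  for (nm in names(comps)) {
    s <- comps[[nm]]
    if (!inherits(s, "spct")) stop("eyeshine_components: ", nm, " not a spct")
    if (length(s$wl) != length(wl_ref) || any(s$wl != wl_ref))
      stop("eyeshine_components: ", nm, " not on the canonical 380-700/1nm grid")
    if (nm != "sar_narrow" && any(s$value < 0 | s$value > 2))
      stop("eyeshine_components: ", nm, " outside [0, 2]")
    if (nm == "sar_narrow" && any(s$value < 0))
      stop("eyeshine_components: sar_narrow must be non-negative")
  }
  structure(c(comps, list(individual_id = as.character(individual_id))),
            class = "eyeshine_components")
}

#' @export
print.eyeshine_components <- function(x, ...) {
  cat(sprintf("<eyeshine_components> individual %s\n", x$individual_id))
  for (nm in c("sar_narrow", "sar_broad", "pet", "iris", "model_pupil"))
    cat(sprintf("  %-11s mean %.4g\n", nm, mean(x[[nm]]$value)))
  invisible(x)
}

.check_exposure <- function(m, expected, what) {
  if (inherits(m, "spct_meas") && m$exposure != expected)
    stop(sprintf("%s: measurement exposure is '%s', expected '%s'",
                 what, m$exposure, expected))
  invisible(TRUE)
}

#' Broad-sense SAR eyeshine reflectance
#'
#' Reflectance of side-welling light by the exposed stratum argenteum:
#' pupil radiance of a shaded fish divided, wavelength by wavelength, by
#' the radiance of a shaded diffuse white standard at the same location.
#' Shading suppresses the transmitted (PET) component so only the reflected
#' one remains.
#'
#' @param pupil_shaded Pupil radiance under shade ([spct()] or
#'   [measurement()] with exposure `"shaded"`).
#' @param white_shaded Shaded white-standard radiance facing the
#'   instrument; strictly positive.
#' @return A reflectance [spct()].
#' @export
broad_sar_reflectance <- function(pupil_shaded, white_shaded) {
  .check_exposure(pupil_shaded, "shaded", "broad_sar_reflectance")
  .check_exposure(white_shaded, "shaded", "broad_sar_reflectance")
  normalize_to_standard(as_spct(pupil_shaded), as_spct(white_shaded),
                        kind = "reflectance")
}

#' Narrow-sense SAR eyeshine reflectance
#'
#' The purely retroreflective component: coaxially induced pupil radiance
#' divided by the radiance of a coaxially illuminated diffuse white
#' standard. Because a retroreflector is compared against a diffuse
#' surface, values well above 1 are expected under this geometry.
#'
#' @param pupil_coaxial Pupil radiance under coaxial illumination.
#' @param white_coaxial Coaxially illuminated white-standard radiance.
#' @return A reflectance [spct()] (unbounded above).
#' @export
narrow_sar_reflectance <- function(pupil_coaxial, white_coaxial) {
  .check_exposure(pupil_coaxial, "coaxial", "narrow_sar_reflectance")
  .check_exposure(white_coaxial, "coaxial", "narrow_sar_reflectance")
  normalize_to_standard(as_spct(pupil_coaxial), as_spct(white_coaxial),
                        kind = "reflectance")
}

#' PET eyeshine transmittance
#'
#' Transmittance of down-welling light through the dorsal eye wall and
#' pigment epithelium: (exposed pupil radiance minus the SAR-only pupil
#' radiance) divided by the radiance of an exposed white standard parallel
#' to the water surface. The subtrahend is the pupil measured with the
#' down-welling path blocked, which isolates the reflected (SAR)
#' contribution. Negative differences (measurement noise) are clamped to
#' zero; the clamped fraction of wavelengths is attached as attribute
#' `"clamp_fraction"`.
#'
#' @param pupil_exposed Exposed pupil radiance.
#' @param pupil_shaded SAR-only pupil radiance (shaded measurement, or the
#'   broad-SAR contribution rescaled to the exposed side-welling field; see
#'   [decompose_individual()]).
#' @param white_down_exposed Exposed down-welling white-standard radiance
#'   (parallel to surface); strictly positive.
#' @return A transmittance [spct()] with attribute `clamp_fraction`.
#' @export
pet_transmittance <- function(pupil_exposed, pupil_shaded,
                              white_down_exposed) {
  .check_exposure(pupil_exposed, "exposed", "pet_transmittance")
  if (inherits(pupil_exposed, "spct_meas") &&
      inherits(pupil_shaded, "spct_meas") &&
      pupil_exposed$individual_id != pupil_shaded$individual_id)
    stop("pet_transmittance: exposed and shaded pupils are from different individuals")
  exposed <- as_spct(pupil_exposed)
  shaded <- as_spct(pupil_shaded)
  white <- as_spct(white_down_exposed)
  if (any(white$value <= 0))
    stop("pet_transmittance: white-standard radiance must be > 0 everywhere")
  pet <- normalize_to_standard(exposed - shaded, white,
                               kind = "transmittance")
  neg <- pet$value < 0
  pet$value[neg] <- 0
  attr(pet, "clamp_fraction") <- mean(neg)
  pet
}

#' Surface reflectance against a facing white standard
#'
#' Reflectance of the iris, a skin patch or the model pupil: photon
#' radiance normalised by the radiance of the PTFE white standard facing
#' the instrument under the same light field.
#'
#' @param target Radiance of the structure.
#' @param white_facing Facing white-standard radiance; strictly positive.
#' @return A reflectance [spct()].
#' @export
surface_reflectance <- function(target, white_facing) {
  normalize_to_standard(as_spct(target), as_spct(white_facing),
                        kind = "reflectance")
}

#' Decompose one individual's measurement set into eyeshine components
#'
#' Applies the full decomposition protocol to a measurement list (as
#' produced by [read_spectra()] or [make_field_measurements()]): broad SAR
#' from the shaded pupil and shaded side standard; narrow SAR from the
#' coaxial pair (if present); PET from the exposed pupil after subtracting
#' the SAR contribution rescaled to the exposed side-welling field (the
#' shaded pupil measures SAR eyeshine only, so rescaling by the ratio of
#' exposed to shaded side-standard radiance expresses that contribution
#' under exposed illumination; when shading leaves the side-welling light
#' unchanged, as in the laboratory protocol, the rescaling factor is 1 and
#' this is exactly exposed minus shaded); iris and model pupil against the
#' facing exposed side standard.
#'
#' @param measurements List of [measurement()]s for one individual.
#' @param individual_id Identifier to select (default: taken from the
#'   first measurement).
#' @return An [eyeshine_components()] object. When the coaxial pair is
#'   absent, `sar_narrow` is a flat zero spectrum.
#' @export
decompose_individual <- function(measurements, individual_id = NULL) {
  if (is.null(individual_id))
    individual_id <- measurements[[1]]$individual_id
  keep <- vapply(measurements, function(m)
    m$individual_id == individual_id || m$target == "white_standard",
    logical(1))
  ms <- measurements[keep]

  w_side_ex <- find_measurement(ms, "white_standard", "exposed",
                                "facing_instrument")
  w_side_sh <- find_measurement(ms, "white_standard", "shaded",
                                "facing_instrument")
  w_down <- find_measurement(ms, "white_standard", "exposed",
                             "parallel_to_surface")
  p_ex <- find_measurement(ms, "pupil", "exposed", individual_id = individual_id)
  p_sh <- find_measurement(ms, "pupil", "shaded", individual_id = individual_id)

  sar_broad <- broad_sar_reflectance(p_sh, w_side_sh)

  # SAR contribution to the exposed pupil, then PET = (exposed - SAR)/down
  sar_radiance_exposed <- measurement(
    set_kind(as_spct(w_side_ex) * sar_broad, "photon_radiance"),
    target = "pupil", exposure = "shaded", individual_id = individual_id)
  pet <- pet_transmittance(p_ex, sar_radiance_exposed, w_down)

  iris <- surface_reflectance(
    find_measurement(ms, "iris", "exposed", individual_id = individual_id),
    w_side_ex)
  model <- surface_reflectance(
    find_measurement(ms, "model_pupil", "exposed"), w_side_ex)

  has_coax <- any(vapply(ms, function(m)
    m$target == "pupil" && m$exposure == "coaxial", logical(1)))
  sar_narrow <- if (has_coax) {
    narrow_sar_reflectance(
      find_measurement(ms, "pupil", "coaxial", individual_id = individual_id),
      find_measurement(ms, "white_standard", "coaxial"))
  } else flat_spct(0, kind = "reflectance")

  out <- eyeshine_components(sar_narrow = sar_narrow, sar_broad = sar_broad,
                             pet = pet, iris = iris, model_pupil = model,
                             individual_id = individual_id)
  attr(out, "pet_clamp_fraction") <- attr(pet, "clamp_fraction")
  out
}
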