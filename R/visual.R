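#' A1 visual-pigment absorbance template
#'
#' Govardovskii-type alpha-band template for an A1 (rhodopsin) pigment,
#' parameterised only by the wavelength of peak absorbance:
#'
#' \deqn{S(\lambda) = 1 / (e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)}
#'
#' with \eqn{x = \lambda_{max}/\lambda}, A = 69.7, B = 28, C = -14.9,
#' D = 0.674, b = 0.922, c = 1.104 and
#' \eqn{a = 0.8795 + 0.0459 e^{-(\lambda_{max}-300)^2 / 11940}}. The curve
#' is peak-normalised on the requested grid. It stands in for measured
#' receptor sensitivity curves when only the peak wavelength is known.
#'
#' @param lambda_max_nm Peak wavelength, 350--650 nm.
#' @param grid A [wl_grid()] (default canonical).
#' @return A `sensitivity` [spct()] with maximum 1.
#' @export
#' @examples
#' s <- pigment_template(517)
#' s$wl[which.max(s$value)]  # 517
pigment_template <- function(lambda_max_nm, grid = canonical_grid()) {
  if (!is.numeric(lambda_max_nm) || lambda_max_nm < 350 || lambda_max_nm > 650)
    stop("pigment_template: lambda_max_nm must be in [350, 650]")
  wl <- wavelengths(grid)
  x <- lambda_max_nm / wl
  a <- 0.8795 + 0.0459 * exp(-(lambda_max_nm - 300)^2 / 11940)
  v <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
              exp(-14.9 * (1.104 - x)) + 0.674)
  spct(wl, v / max(v), "sensitivity")
}

#' Logistic short-wavelength ocular-media cutoff
#'
#' Optional ocular-media transmittance model: a logistic ramp from opaque
#' to transparent, `1 / (1 + exp(-(lambda - half) * slope))`.
#'
#' @param half_nm Wavelength of half transmission (default 400 nm).
#' @param slope Steepness per nm (default 0.1).
#' @param grid A [wl_grid()].
#' @return A `transmittance` [spct()] in [0, 1].
#' @export
ocular_media_logistic <- function(half_nm = 400, slope = 0.1,
                                  grid = canonical_grid()) {
  wl <- wavelengths(grid)
  spct(wl, 1 / (1 + exp(-(wl - half_nm) * slope)), "transmittance")
}

#' Photoreceptor class
#'
#' @param lambda_max_nm Peak sensitivity wavelength (nm), inside the grid.
#' @param relative_density Relative abundance of the class in the retina
#'   (> 0); noise scales with `1/sqrt(density)`.
#' @param sensitivity Peak-normalised `sensitivity` [spct()]; defaults to
#'   [pigment_template()] at `lambda_max_nm`.
#' @param grid Grid used when building the default sensitivity.
#' @return An object of class `"photoreceptor"`.
#' @export
photoreceptor <- function(lambda_max_nm, relative_density,
                          sensitivity = NULL, grid = canonical_grid()) {
  if (relative_density <= 0)
    stop("photoreceptor: relative_density must be > 0")
  wl <- wavelengths(grid)
  if (lambda_max_nm < min(wl) || lambda_max_nm > max(wl))
    stop("photoreceptor: lambda_max_nm outside the wavelength grid")
  if (is.null(sensitivity)) sensitivity <- pigment_template(lambda_max_nm, grid)
  stopifnot(inherits(sensitivity, "spct"))
  if (abs(max(sensitivity$value) - 1) > 1e-8)
    stop("photoreceptor: sensitivity must be peak-normalised to 1")
  structure(list(lambda_max_nm = lambda_max_nm,
                 relative_density = relative_density,
                 sensitivity = sensitivity),
            class = "photoreceptor")
}

#' Prey-observer visual system
#'
#' Trichromatic receptor set plus the parameters of the receptor-noise
#' model: relative receptor densities (noise in class i is
#' `weber * sqrt(max(density)/density_i)`, anchoring the Weber fraction to
#' the most abundant class), ocular-media transmittance, and the two
#' double-cone members whose summed quantum catch forms the luminance
#' channel. The default is the triplefin *Tripterygion delaisi*, a common
#' scorpionfish prey: SWS 468 nm, MWS 517 nm, LWS 530 nm, foveal densities
#' 1:4:4 and Weber fraction 0.05, with sensitivities built from the A1
#' pigment template.
#'
#' @param lambda_max Named numeric vector of peak wavelengths for `sws`,
#'   `mws`, `lws`.
#' @param densities Relative densities in the same order.
#' @param weber_fraction Weber fraction of the most abundant class (> 0).
#' @param ocular_media Optional `transmittance` [spct()] in [0, 1]; default
#'   flat 1 (transparent media).
#' @param luminance_members Receptor names summed for the luminance
#'   (double-cone) channel.
#' @param sensitivities Optional named list of measured peak-normalised
#'   sensitivity [spct()]s replacing the template curves.
#' @param grid A [wl_grid()].
#' @return An object of class `"visual_system"`.
#' @export
visual_system <- function(lambda_max = c(sws = 468, mws = 517, lws = 530),
                          densities = c(sws = 1, mws = 4, lws = 4),
                          weber_fraction = 0.05,
                          ocular_media = NULL,
                          luminance_members = c("mws", "lws"),
                          sensitivities = NULL,
                          grid = canonical_grid()) {
  stopifnot(length(lambda_max) == length(densities))
  if (is.null(names(lambda_max)))
    names(lambda_max) <- names(densities)
  if (weber_fraction <= 0)
    stop("visual_system: weber_fraction must be > 0")
  if (is.null(ocular_media)) ocular_media <- flat_spct(1, grid, "transmittance")
  stopifnot(inherits(ocular_media, "spct"))
  if (any(ocular_media$value < 0 | ocular_media$value > 1))
    stop("visual_system: ocular media transmittance must be in [0, 1]")
  if (!all(luminance_members %in% names(lambda_max)))
    stop("visual_system: luminance_members must name receptors")
  receptors <- Map(function(nm, lm, d)
    photoreceptor(lm, d, sensitivity = sensitivities[[nm]], grid = grid),
    names(lambda_max), lambda_max, densities)
  names(receptors) <- names(lambda_max)
  structure(list(receptors = receptors,
                 weber_fraction = weber_fraction,
                 ocular_media = ocular_media,
                 luminance_members = luminance_members),
            class = "visual_system")
}

#' @rdname visual_system
#' @export
triplefin_visual_system <- function(grid = canonical_grid())
  visual_system(grid = grid)

#' @export
print.visual_system <- function(x, ...) {
  lmax <- vapply(x$receptors, `[[`, numeric(1), "lambda_max_nm")
  dens <- vapply(x$receptors, `[[`, numeric(1), "relative_density")
  cat("<visual_system>\n")
  cat("  receptors:",
      paste(sprintf("%s %g nm (density %g)", names(lmax), lmax, dens),
            collapse = ", "), "\n")
  cat(sprintf("  Weber fraction %.3g; luminance = %s\n", x$weber_fraction,
              paste(x$luminance_members, collapse = " + ")))
  invisible(x)
}

# receptor noise e_i = w * sqrt(eta_max / eta_i)
.receptor_noise <- function(vs) {
  dens <- vapply(vs$receptors, `[[`, numeric(1), "relative_density")
  vs$weber_fraction * sqrt(max(dens) / dens)
}

#' Quantum catch of one receptor class
#'
#' Photon flux absorbed by receptor class i: the trapezoidal integral over
#' the canonical window of stimulus radiance times receptor sensitivity
#' times ocular-media transmittance.
#'
#' @param radiance Non-negative `photon_radiance` [spct()] (or
#'   [measurement()]).
#' @param vs A [visual_system()].
#' @param receptor Receptor name, e.g. `"mws"`.
#' @return A number.
#' @export
quantum_catch <- function(radiance, vs, receptor) {
  stopifnot(inherits(vs, "visual_system"))
  radiance <- as_spct(radiance)
  if (any(radiance$value < 0))
    stop("quantum_catch: radiance must be non-negative")
  if (!receptor %in% names(vs$receptors))
    stop("quantum_catch: unknown receptor '", receptor, "'")
  sens <- vs$receptors[[receptor]]$sensitivity
  integrand <- radiance * sens * vs$ocular_media
  integrate_spectrum(set_kind(integrand, radiance$kind))
}

#' Quantum catches of all receptor classes
#' @inheritParams quantum_catch
#' @return Named numeric vector, one catch per receptor.
#' @export
quantum_catches <- function(radiance, vs) {
  vapply(names(vs$receptors), function(r) quantum_catch(radiance, vs, r),
         numeric(1))
}

#' Receptor-noise chromatic distance (JND)
#'
#' Chromatic contrast between two stimuli under the receptor-noise-limited
#' model, in just-noticeable differences: receptor signals are the log
#' catch ratios \eqn{\Delta f_i = \ln(Q_{i,a}/Q_{i,b})}, class noise is
#' \eqn{e_i = w \sqrt{\eta_{max}/\eta_i}}, and for a trichromat
#'
#' \deqn{\Delta S^2 = \frac{e_1^2(\Delta f_3-\Delta f_2)^2 +
#'   e_2^2(\Delta f_3-\Delta f_1)^2 + e_3^2(\Delta f_2-\Delta f_1)^2}
#'   {(e_1 e_2)^2 + (e_1 e_3)^2 + (e_2 e_3)^2}}
#'
#' (implemented in its general n-receptor form). Values above 1 indicate a
#' discernible difference. A uniform intensity change (all catches scaled
#' by the same factor) gives exactly 0: the model is purely chromatic.
#'
#' @param catches_a,catches_b Positive per-receptor quantum catches, in the
#'   receptor order of `vs`.
#' @param vs A [visual_system()].
#' @return Non-negative number (JND).
#' @export
#' @examples
#' vs <- triplefin_visual_system()
#' chromatic_jnd(c(1, 1, 1), c(1, 1, exp(1)), vs)  # 14.907
chromatic_jnd <- function(catches_a, catches_b, vs) {
  stopifnot(inherits(vs, "visual_system"))
  n <- length(vs$receptors)
  if (length(catches_a) != n || length(catches_b) != n)
    stop("chromatic_jnd: need one catch per receptor")
  if (any(catches_a <= 0) || any(catches_b <= 0))
    stop("chromatic_jnd: quantum catches must be strictly positive")
  e <- .receptor_noise(vs)
  df <- log(catches_a / catches_b)
  # general receptor-noise solution: products over the complementary classes
  num <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    num <- num + prod(e[-c(i, j)])^2 * (df[i] - df[j])^2
  }
  den <- sum(vapply(seq_len(n), function(i) prod(e[-i])^2, numeric(1)))
  sqrt(num / den)
}

#' Per-wavelength Michelson contrast spectrum
#'
#' Signed Michelson contrast `(a - b) / (a + b)` at each wavelength;
#' positive where `a` (e.g. the pupil) is brighter than `b` (e.g. the
#' iris). Zero means no contrast. Requires `a + b > 0` everywhere.
#'
#' @param a,b Non-negative [spct()]s on a common grid.
#' @return A dimensionless [spct()] with values in [-1, 1].
#' @export
michelson_spectrum <- function(a, b) {
  a <- as_spct(a); b <- as_spct(b)
  if (!.same_wl(a, b)) stop("michelson_spectrum: different grids")
  if (any(a$value < 0) || any(b$value < 0))
    stop("michelson_spectrum: spectra must be non-negative")
  s <- a$value + b$value
  if (any(s == 0))
    stop("michelson_spectrum: contrast undefined where a + b = 0")
  new_spct(a$wl, (a$value - b$value) / s, "irradiance_proxy",
           units = "dimensionless")
}

#' Achromatic (luminance) Michelson contrast
#'
#' Absolute Michelson contrast of the luminance channel, where luminance is
#' the summed quantum catch of the two double-cone members
#' (`L = Q_mws + Q_lws` by default):
#' `|L_a - L_b| / (L_a + L_b)`, in [0, 1].
#'
#' @param radiance_a,radiance_b Non-negative `photon_radiance` [spct()]s.
#' @param vs A [visual_system()].
#' @return A number in [0, 1].
#' @export
achromatic_contrast <- function(radiance_a, radiance_b, vs) {
  stopifnot(inherits(vs, "visual_system"))
  lum <- function(r) sum(vapply(vs$luminance_members, function(m)
    quantum_catch(r, vs, m), numeric(1)))
  la <- lum(radiance_a); lb <- lum(radiance_b)
  if (la + lb == 0)
    stop("achromatic_contrast: both luminance catches are zero; contrast undefined")
  abs(la - lb) / (la + lb)
}

#' Viewing scenario
#'
#' A scenario scales the exposed illuminants by factors in [0, 1]:
#' `down_factor` for the down-welling light reaching the fish (drives PET
#' eyeshine) and `side_factor` for the side-welling light (drives SAR
#' eyeshine and lights iris, skin and model pupil). The three default
#' scenarios of [default_scenarios()] are: s1, predator and prey both in
#' the open (1, 1); s2, prey shaded or against a dark background so the
#' side-welling field is reduced (1, shade); s3, predator shaded so the
#' down-welling path is reduced (shade, 1).
#'
#' @param name Scenario label.
#' @param down_factor,side_factor Numbers in [0, 1].
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(name, down_factor, side_factor) {
  if (down_factor < 0 || down_factor > 1 || side_factor < 0 || side_factor > 1)
    stop("scenario_spec: factors must be in [0, 1]")
  structure(list(name = name, down_factor = down_factor,
                 side_factor = side_factor), class = "scenario_spec")
}

#' @rdname scenario_spec
#' @param shade_fraction Fraction of light remaining under shade, used for
#'   the shaded factor in s2 and s3 (default 0.55, the generator default).
#' @export
default_scenarios <- function(shade_fraction = 0.55) {
  list(s1 = scenario_spec("s1_both_exposed", 1, 1),
       s2 = scenario_spec("s2_viewer_shaded", 1, shade_fraction),
       s3 = scenario_spec("s3_predator_shaded", shade_fraction, 1))
}

#' Run one camouflage scenario
#'
#' Assembles the radiances seen by the prey under a scenario's illuminants
#' (pupil via [predict_pupil_radiance()]-style forward optics with the
#' scenario factors applied, iris and model pupil as lit surfaces) and
#' returns chromatic JND and absolute achromatic Michelson contrast for
#' the natural pupil against the iris and for the dark model pupil against
#' the iris. The model-vs-iris achromatic contrast is the same in every
#' scenario because both surfaces scale with the side-welling factor only.
#'
#' @param components An [eyeshine_components()] object.
#' @param lf A [lightfield()].
#' @param scenario A [scenario_spec()].
#' @param vs A [visual_system()].
#' @return A list of class `"scenario_result"` with elements `natural` and
#'   `model`, each holding `chromatic_jnd`, `achromatic_michelson`,
#'   `catches_a` (the pupil) and `catches_b` (the iris), plus `scenario`
#'   and `depth_m`.
#' @export
run_scenario <- function(components, lf, scenario, vs) {
  stopifnot(inherits(components, "eyeshine_components"),
            inherits(lf, "lightfield"),
            inherits(scenario, "scenario_spec"),
            inherits(vs, "visual_system"))
  side <- lf$side_welling_exposed * scenario$side_factor
  down <- lf$down_welling * scenario$down_factor
  pupil <- set_kind(side * components$sar_broad + down * components$pet,
                    "photon_radiance")
  iris <- set_kind(side * components$iris, "photon_radiance")
  model <- set_kind(side * components$model_pupil, "photon_radiance")

  if (sum(side$value) == 0 && sum(down$value) == 0)
    stop("run_scenario: all illuminants are zero; contrast undefined")

  contrast_pair <- function(a, b) {
    qa <- quantum_catches(a, vs); qb <- quantum_catches(b, vs)
    list(chromatic_jnd = chromatic_jnd(qa, qb, vs),
         achromatic_michelson = achromatic_contrast(a, b, vs),
         catches_a = qa, catches_b = qb)
  }
  structure(list(natural = contrast_pair(pupil, iris),
                 model = contrast_pair(model, iris),
                 scenario = scenario$name,
                 depth_m = lf$depth_m),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s at %g m\n", x$scenario, x$depth_m))
  cat(sprintf("  natural pupil vs iris: JND %.2f, |Cm| %.2f\n",
              x$natural$chromatic_jnd, x$natural$achromatic_michelson))
  cat(sprintf("  model pupil vs iris:   JND %.2f, |Cm| %.2f\n",
              x$model$chromatic_jnd, x$model$achromatic_michelson))
  invisible(x)
}

#' Pairwise achromatic contrasts among skin patches
#'
#' Absolute luminance Michelson contrast for every unordered pair of skin
#' patches, each patch rendered as a lit surface under the side-welling
#' field. This is the body-patterning contrast distribution a concealed
#' pupil should fall inside.
#'
#' @param patches List of at least two reflectance [spct()]s.
#' @param lf A [lightfield()].
#' @param vs A [visual_system()].
#' @return Numeric vector of `n(n-1)/2` contrasts.
#' @export
skin_patch_contrasts <- function(patches, lf, vs) {
  stopifnot(inherits(lf, "lightfield"), inherits(vs, "visual_system"))
  if (length(patches) < 2L)
    stop("skin_patch_contrasts: need at least 2 patches")
  rad <- lapply(patches, function(p)
    set_kind(lf$side_welling_exposed * as_spct(p), "photon_radiance"))
  n <- length(rad)
  out <- numeric(0)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    out <- c(out, achromatic_contrast(rad[[i]], rad[[j]], vs))
  out
}
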