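#' Underwater light field at one depth
#'
#' Paired illuminant radiances measured (or simulated) with diffuse white
#' standards: a down-welling proxy (standard parallel to the water
#' surface, exposed) and side-welling proxies (standards perpendicular to
#' the surface, facing the instrument), one exposed and one shaded. A
#' warning is issued when the shaded side-welling exceeds the exposed one
#' anywhere, since a shade can only remove light.
#'
#' @param down_welling,side_welling_exposed,side_welling_shaded
#'   `photon_radiance` [spct()]s on the canonical grid, non-negative.
#' @param depth_m Depth in metres.
#' @return An object of class `"lightfield"`.
#' @export
lightfield <- function(down_welling, side_welling_exposed,
                       side_welling_shaded, depth_m) {
  comps <- list(down_welling = down_welling,
                side_welling_exposed = side_welling_exposed,
                side_welling_shaded = side_welling_shaded)
  wl_ref <- wavelengths(canonical_grid())
  for (nm in names(comps)) {
    s <- comps[[nm]]
    if (!inherits(s, "spct")) stop("lightfield: ", nm, " not a spct")
    if (s$kind != "photon_radiance")
      stop("lightfield: ", nm, " must be photon_radiance")
    if (length(s$wl) != length(wl_ref) || any(s$wl != wl_ref))
      stop("lightfield: ", nm, " not on the canonical grid")
    if (any(s$value < 0)) stop("lightfield: ", nm, " has negative radiance")
  }
  if (any(side_welling_shaded$value > side_welling_exposed$value))
    warning("lightfield: shaded side-welling exceeds exposed side-welling at some wavelengths")
  structure(c(comps, list(depth_m = as.numeric(depth_m))),
            class = "lightfield")
}

#' @export
print.lightfield <- function(x, ...) {
  cat(sprintf("<lightfield> depth %g m\n", x$depth_m))
  for (nm in c("down_welling", "side_welling_exposed", "side_welling_shaded"))
    cat(sprintf("  %-22s integral %.4g\n", nm,
                integrate_spectrum(x[[nm]])))
  invisible(x)
}

.side_for <- function(lf, exposure) {
  switch(exposure,
         exposed = lf$side_welling_exposed,
         shaded = lf$side_welling_shaded,
         stop("exposure must be 'exposed' or 'shaded'"))
}

#' Forward-predict pupil radiance from component spectra
#'
#' Reverse-engineers the field pupil radiance from laboratory component
#' estimates and measured illuminants. SAR eyeshine reflects the
#' side-welling field; PET eyeshine transmits the down-welling field. When
#' the fish is shaded the down-welling path is blocked and pupil radiance
#' involves SAR eyeshine only:
#'
#' exposed: `side_exposed * sar_broad + down * pet`;
#' shaded: `side_shaded * sar_broad`.
#'
#' @param components An [eyeshine_components()] object.
#' @param lf A [lightfield()].
#' @param exposure `"exposed"` or `"shaded"`.
#' @return A `photon_radiance` [spct()].
#' @export
predict_pupil_radiance <- function(components, lf, exposure) {
  stopifnot(inherits(components, "eyeshine_components"),
            inherits(lf, "lightfield"))
  exposure <- match.arg(exposure, c("exposed", "shaded"))
  if (is.null(components$sar_broad) || is.null(components$pet))
    stop("predict_pupil_radiance: missing component spectra")
  out <- if (exposure == "exposed")
    lf$side_welling_exposed * components$sar_broad +
      lf$down_welling * components$pet
  else
    lf$side_welling_shaded * components$sar_broad
  set_kind(out, "photon_radiance")
}

#' Forward-predict iris radiance from its reflectance
#'
#' The iris is an ordinary diffuse surface lit by the side-welling field:
#' `side_welling(exposure) * iris reflectance`.
#'
#' @inheritParams predict_pupil_radiance
#' @return A `photon_radiance` [spct()].
#' @export
predict_iris_radiance <- function(components, lf, exposure) {
  stopifnot(inherits(components, "eyeshine_components"),
            inherits(lf, "lightfield"))
  exposure <- match.arg(exposure, c("exposed", "shaded"))
  if (is.null(components$iris))
    stop("predict_iris_radiance: missing iris reflectance")
  set_kind(.side_for(lf, exposure) * components$iris, "photon_radiance")
}

#' Log-ratio match between predicted and measured radiance
#'
#' The reconstruction score: mean over wavelengths of
#' `log10(predicted) / log10(measured)`, where 1 is a perfect match. The
#' metric is computed in the units the radiances are supplied in (it is
#' not scale invariant) and diverges where `log10(measured)` approaches
#' zero, i.e. where the measured radiance is near 1 in its units; such
#' wavelengths raise an error rather than being silently dropped.
#'
#' @param predicted,measured Strictly positive [spct()]s (or
#'   [measurement()]s) on a common grid.
#' @param eps Guard threshold on `|log10(measured)|` (default 1e-3).
#' @return A number; 1 means the curves match.
#' @export
log_ratio_match <- function(predicted, measured, eps = 1e-3) {
  p <- as_spct(predicted); m <- as_spct(measured)
  if (!.same_wl(p, m))
    stop("log_ratio_match: spectra on different grids")
  if (any(p$value <= 0) || any(m$value <= 0))
    stop("log_ratio_match: radiances must be strictly positive")
  lm10 <- log10(m$value)
  if (any(abs(lm10) <= eps))
    stop("log_ratio_match: |log10(measured)| <= ", eps,
         " at some wavelengths; the ratio is undefined there (measured",
         " radiance too close to 1 in its units)")
  mean(log10(p$value) / lm10)
}
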