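#' @keywords internal
"_PACKAGE"

.SPCT_KINDS <- c("photon_radiance", "reflectance", "transmittance",
                 "sensitivity", "irradiance_proxy")

.default_units <- function(kind) {
  switch(kind,
         photon_radiance = "photons s-1 m-2 sr-1 nm-1",
         irradiance_proxy = "photons s-1 m-2 nm-1",
         "dimensionless")
}

#' Wavelength grid
#'
#' A regular wavelength grid in nanometres. The canonical analysis window
#' used throughout the package is 380--700 nm at a 1-nm step: radiance is
#' integrated over that range and all spectra are resampled onto it before
#' any spectral arithmetic.
#'
#' @param start_nm,stop_nm Window limits in nm (`start_nm < stop_nm`).
#' @param step_nm Grid step in nm (> 0).
#' @return An object of class `"wl_grid"`.
#' @seealso [canonical_grid()], [wavelengths()]
#' @export
#' @examples
#' g <- wl_grid(400, 600, 5)
#' head(wavelengths(g))
wl_grid <- function(start_nm = 380, stop_nm = 700, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (!(start_nm < stop_nm)) stop("wl_grid: start_nm must be < stop_nm")
  if (!(step_nm > 0)) stop("wl_grid: step_nm must be > 0")
  structure(list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm),
            class = "wl_grid")
}

#' @rdname wl_grid
#' @export
canonical_grid <- function() wl_grid(380, 700, 1)

#' Wavelength vector of a grid
#' @param g A [wl_grid()].
#' @return Numeric vector of wavelengths (nm).
#' @export
wavelengths <- function(g) {
  stopifnot(inherits(g, "wl_grid"))
  seq(g$start_nm, g$stop_nm, by = g$step_nm)
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %g-%g nm, step %g nm (%d samples)\n",
              x$start_nm, x$stop_nm, x$step_nm, length(wavelengths(x))))
  invisible(x)
}

new_spct <- function(wl, value, kind, units = NULL) {
  structure(list(wl = wl, value = value, kind = kind,
                 units = if (is.null(units)) .default_units(kind) else units),
            class = "spct")
}

#' Spectra
#'
#' A spectrum is a set of per-wavelength values with a declared quantity
#' kind: photon radiance (photons s-1 m-2 sr-1 nm-1), dimensionless
#' reflectance or transmittance (expressed relative to a diffuse PTFE white
#' standard), receptor sensitivity (peak-normalised), or an irradiance
#' proxy. Reflectance measured against a diffuse standard may legitimately
#' exceed 1 for retroreflective surfaces viewed coaxially.
#'
#' Arithmetic between spectra on the same wavelength grid works with the
#' usual operators (`+`, `-`, `*`, `/`, and scalars); the result keeps the
#' kind of the left spectrum operand, which helpers such as
#' [normalize_to_standard()] then set explicitly.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param value Numeric vector of the same length; must be finite.
#' @param kind One of `"photon_radiance"`, `"reflectance"`,
#'   `"transmittance"`, `"sensitivity"`, `"irradiance_proxy"`.
#' @param units Unit string; defaults by kind.
#' @return An object of class `"spct"`.
#' @export
#' @examples
#' s <- spct(380:700, rep(1, 321), "photon_radiance")
#' integrate_spectrum(s)  # 320 (value-units x nm)
spct <- function(wavelength, value, kind = "photon_radiance", units = NULL) {
  kind <- match.arg(kind, .SPCT_KINDS)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("spct: wavelength and value lengths differ")
  if (length(wavelength) < 2L) stop("spct: need at least 2 samples")
  if (any(!is.finite(wavelength)) || any(!is.finite(value)))
    stop("spct: non-finite wavelength or value")
  if (any(diff(wavelength) <= 0))
    stop("spct: wavelengths must be strictly increasing")
  new_spct(wavelength, value, kind, units)
}

#' Flat spectrum on a grid
#'
#' Convenience constructor for a constant spectrum, used for idealised
#' illuminants and flat reflectances.
#'
#' @param value Constant value.
#' @param grid A [wl_grid()] (default canonical).
#' @inheritParams spct
#' @return A [spct()].
#' @export
flat_spct <- function(value, grid = canonical_grid(),
                      kind = "photon_radiance") {
  wl <- wavelengths(grid)
  spct(wl, rep(value, length(wl)), kind)
}

#' @export
print.spct <- function(x, ...) {
  cat(sprintf("<spct:%s> %g-%g nm (%d samples), range [%.4g, %.4g] %s\n",
              x$kind, min(x$wl), max(x$wl), length(x$wl),
              min(x$value), max(x$value), x$units))
  invisible(x)
}

#' @export
as.data.frame.spct <- function(x, ...) {
  data.frame(wavelength_nm = x$wl, value = x$value)
}

#' @export
plot.spct <- function(x, ..., xlab = "Wavelength (nm)", ylab = x$kind,
                      type = "l") {
  graphics::plot(x$wl, x$value, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

.same_wl <- function(a, b) {
  length(a$wl) == length(b$wl) && all(a$wl == b$wl)
}

#' @export
Ops.spct <- function(e1, e2) {
  if (missing(e2)) {
    stopifnot(inherits(e1, "spct"))
    return(new_spct(e1$wl, get(.Generic)(e1$value), e1$kind, e1$units))
  }
  s1 <- inherits(e1, "spct"); s2 <- inherits(e2, "spct")
  if (s1 && s2) {
    if (!.same_wl(e1, e2))
      stop("spct arithmetic: spectra are on different wavelength grids")
    v <- get(.Generic)(e1$value, e2$value)
    ref <- e1
  } else if (s1) {
    if (!(is.numeric(e2) && length(e2) %in% c(1L, length(e1$wl))))
      stop("spct arithmetic: incompatible operand")
    v <- get(.Generic)(e1$value, e2)
    ref <- e1
  } else {
    if (!(is.numeric(e1) && length(e1) %in% c(1L, length(e2$wl))))
      stop("spct arithmetic: incompatible operand")
    v <- get(.Generic)(e1, e2$value)
    ref <- e2
  }
  if (.Generic %in% c("==", "!=", "<", ">", "<=", ">=")) return(v)
  new_spct(ref$wl, v, ref$kind, ref$units)
}

#' Change the declared kind of a spectrum
#' @param s A [spct()].
#' @param kind New kind.
#' @return The spectrum with kind (and default units) replaced.
#' @export
set_kind <- function(s, kind) {
  stopifnot(inherits(s, "spct"))
  kind <- match.arg(kind, .SPCT_KINDS)
  new_spct(s$wl, s$value, kind)
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation onto a target grid. Extrapolation beyond the source
#' range is refused: illuminant and reflectance spectra cannot be invented
#' outside the measured window.
#'
#' @param s A [spct()].
#' @param grid Target [wl_grid()].
#' @return A [spct()] on `grid`, kind preserved.
#' @export
resample <- function(s, grid = canonical_grid()) {
  stopifnot(inherits(s, "spct"), inherits(grid, "wl_grid"))
  wl <- wavelengths(grid)
  if (min(wl) < min(s$wl) || max(wl) > max(s$wl))
    stop(sprintf(
      "resample: target grid %g-%g nm extends beyond source range %g-%g nm",
      min(wl), max(wl), min(s$wl), max(s$wl)))
  v <- stats::approx(s$wl, s$value, xout = wl, method = "linear")$y
  new_spct(wl, v, s$kind, s$units)
}

.window_bounds <- function(window) {
  if (inherits(window, "wl_grid")) c(window$start_nm, window$stop_nm)
  else if (is.numeric(window) && length(window) == 2L) sort(window)
  else stop("window must be a wl_grid or a numeric length-2 range")
}

#' Integrate a spectrum over a wavelength window
#'
#' Trapezoidal integral of the spectral values over wavelength, in
#' value-units times nm. The default window is the full span of the
#' spectrum; total reflectance in this package integrates radiance over
#' 380--700 nm.
#'
#' @param s A [spct()].
#' @param window Optional [wl_grid()] or numeric `c(lo, hi)` inside the
#'   spectrum's span.
#' @return A number.
#' @export
integrate_spectrum <- function(s, window = NULL) {
  stopifnot(inherits(s, "spct"))
  wl <- s$wl; v <- s$value
  if (!is.null(window)) {
    b <- .window_bounds(window)
    if (b[1] >= b[2]) stop("integrate_spectrum: empty window")
    if (b[1] < min(wl) || b[2] > max(wl))
      stop("integrate_spectrum: window outside spectrum span")
    keep <- wl >= b[1] & wl <= b[2]
    wl_in <- wl[keep]; v_in <- v[keep]
    # add interpolated end points when the window cuts between samples
    if (length(wl_in) == 0L || wl_in[1] > b[1]) {
      v_in <- c(stats::approx(wl, v, xout = b[1])$y, v_in)
      wl_in <- c(b[1], wl_in)
    }
    if (wl_in[length(wl_in)] < b[2]) {
      v_in <- c(v_in, stats::approx(wl, v, xout = b[2])$y)
      wl_in <- c(wl_in, b[2])
    }
    wl <- wl_in; v <- v_in
  }
  if (length(wl) < 2L) stop("integrate_spectrum: empty window")
  pracma::trapz(wl, v)
}

#' Normalise a radiance spectrum by a white-standard radiance
#'
#' Element-wise ratio of a target photon radiance to the radiance of a
#' diffuse white standard measured under the same light field, yielding
#' reflectance (or transmittance, per the caller). Under coaxial geometry a
#' retroreflecting pupil normalised by a diffuse standard readily exceeds 1.
#'
#' @param target,standard [spct()] photon radiances on a common grid;
#'   standard values must be strictly positive.
#' @param kind `"reflectance"` (default) or `"transmittance"`.
#' @return A dimensionless [spct()].
#' @export
normalize_to_standard <- function(target, standard, kind = "reflectance") {
  stopifnot(inherits(target, "spct"), inherits(standard, "spct"))
  kind <- match.arg(kind, c("reflectance", "transmittance"))
  if (target$kind != "photon_radiance" || standard$kind != "photon_radiance")
    stop("normalize_to_standard: both spectra must be photon_radiance")
  if (!.same_wl(target, standard))
    stop("normalize_to_standard: spectra on different grids")
  if (any(standard$value <= 0))
    stop("normalize_to_standard: white-standard radiance must be > 0 everywhere")
  new_spct(target$wl, target$value / standard$value, kind)
}

#' Total reflectance over a wavelength window
#'
#' Ratio of the integrated pupil radiance to the integrated white-standard
#' radiance over the window (default 380--700 nm). This is the ratio of
#' integrals, not the integral of the spectral ratio, so a light-adapted
#' scorpionfish pupil measured coaxially can score far above 1 (values near
#' 30 relative to a diffuse standard).
#'
#' @param pupil,standard [spct()] photon radiances.
#' @param window Optional integration window ([wl_grid()] or `c(lo, hi)`).
#' @return A dimensionless number.
#' @export
total_reflectance <- function(pupil, standard, window = NULL) {
  stopifnot(inherits(pupil, "spct"), inherits(standard, "spct"))
  if (pupil$kind != "photon_radiance" || standard$kind != "photon_radiance")
    stop("total_reflectance: both spectra must be photon_radiance")
  denom <- integrate_spectrum(standard, window)
  if (denom <= 0) stop("total_reflectance: standard integral must be > 0")
  integrate_spectrum(pupil, window) / denom
}
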