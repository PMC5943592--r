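.TARGETS <- c("pupil", "iris", "skin", "white_standard", "model_pupil")
.EXPOSURES <- c("exposed", "shaded", "coaxial")
.ORIENTATIONS <- c("facing_instrument", "parallel_to_surface", "none")

.META_COLS <- c("individual_id", "target", "exposure", "standard_orientation",
                "depth_m", "time_min")

#' Spectroradiometric measurement
#'
#' A measured photon-radiance spectrum plus the metadata that the eyeshine
#' decomposition needs: which structure was measured (pupil, iris, skin,
#' white standard or the black model pupil), under which exposure (exposed
#' to the full light field, shaded, or coaxially illuminated in a dark
#' room), how a white standard was oriented (facing the instrument as a
#' side-welling proxy, or parallel to the water surface as a down-welling
#' proxy), the depth, the individual, and the dark-adaptation clock for
#' time series.
#'
#' @param spectrum A [spct()], normally `photon_radiance`.
#' @param target One of `"pupil"`, `"iris"`, `"skin"`, `"white_standard"`,
#'   `"model_pupil"`.
#' @param exposure One of `"exposed"`, `"shaded"`, `"coaxial"`.
#' @param standard_orientation `"facing_instrument"`,
#'   `"parallel_to_surface"` or `"none"`; white standards must declare an
#'   orientation other than `"none"`.
#' @param depth_m Depth in metres (NA for laboratory measurements).
#' @param individual_id Identifier of the fish (or patch, suffixed).
#' @param time_min Optional dark-adaptation time in minutes.
#' @return An object of class `"spct_meas"`.
#' @export
measurement <- function(spectrum, target, exposure,
                        standard_orientation = "none",
                        depth_m = NA_real_, individual_id = "ind1",
                        time_min = NA_real_) {
  stopifnot(inherits(spectrum, "spct"))
  target <- match.arg(target, .TARGETS)
  exposure <- match.arg(exposure, .EXPOSURES)
  standard_orientation <- match.arg(standard_orientation, .ORIENTATIONS)
  if (target == "white_standard" && standard_orientation == "none")
    stop("measurement: white_standard requires a standard_orientation")
  structure(list(spectrum = spectrum, target = target, exposure = exposure,
                 standard_orientation = standard_orientation,
                 depth_m = as.numeric(depth_m),
                 individual_id = as.character(individual_id),
                 time_min = as.numeric(time_min)),
            class = "spct_meas")
}

#' @export
print.spct_meas <- function(x, ...) {
  cat(sprintf("<measurement> %s/%s, individual %s%s%s\n",
              x$target, x$exposure, x$individual_id,
              if (is.na(x$depth_m)) "" else sprintf(", %g m", x$depth_m),
              if (is.na(x$time_min)) "" else sprintf(", t=%g min", x$time_min)))
  print(x$spectrum)
  invisible(x)
}

.meas_key <- function(m) {
  paste(m$individual_id, m$target, m$exposure, m$standard_orientation,
        m$depth_m, m$time_min, sep = ".")
}

as_spct <- function(x) {
  if (inherits(x, "spct_meas")) x$spectrum
  else if (inherits(x, "spct")) x
  else stop("expected a spct or a measurement")
}

#' Read spectral measurements from a long-format CSV file
#'
#' The file must have columns `wavelength_nm` and `value` plus the metadata
#' columns `individual_id`, `target` and `exposure`; `standard_orientation`,
#' `depth_m` and `time_min` are optional. One file may hold many
#' measurements, keyed by the combination of metadata columns; wavelengths
#' are sorted ascending within each group. Negative radiance values
#' (sensor noise) are clamped to zero with a warning reporting how many.
#'
#' @param path Path to a CSV file (comma separated, `.` decimal, UTF-8).
#' @return A named list of [measurement()] objects.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "value", "individual_id", "target", "exposure")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_spectra: missing required columns: ",
         paste(miss, collapse = ", "))
  if (!"standard_orientation" %in% names(df)) df$standard_orientation <- "none"
  if (!"depth_m" %in% names(df)) df$depth_m <- NA_real_
  if (!"time_min" %in% names(df)) df$time_min <- NA_real_

  n_neg <- sum(df$value < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warning(sprintf(
      "read_spectra: clamped %d negative value(s) to 0 (sensor noise)", n_neg))
    df$value[df$value < 0] <- 0
  }

  key <- paste(df$individual_id, df$target, df$exposure,
               df$standard_orientation, df$depth_m, df$time_min, sep = ".")
  out <- lapply(split(df, key), function(g) {
    if (anyDuplicated(g$wavelength_nm))
      stop(sprintf(
        "read_spectra: duplicate wavelengths in group %s/%s/%s",
        g$individual_id[1], g$target[1], g$exposure[1]))
    g <- g[order(g$wavelength_nm), ]
    measurement(spct(g$wavelength_nm, g$value, "photon_radiance"),
                target = g$target[1], exposure = g$exposure[1],
                standard_orientation = g$standard_orientation[1],
                depth_m = g$depth_m[1], individual_id = g$individual_id[1],
                time_min = g$time_min[1])
  })
  names(out) <- vapply(out, .meas_key, character(1))
  out
}

#' Write spectral measurements to a long-format CSV file
#'
#' Inverse of [read_spectra()]. Values are written with 17 significant
#' digits so a write/read round trip reproduces them bit-identically.
#'
#' @param measurements A list of [measurement()] objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(measurements, path) {
  if (inherits(measurements, "spct_meas")) measurements <- list(measurements)
  stopifnot(all(vapply(measurements, inherits, logical(1), "spct_meas")))
  rows <- lapply(measurements, function(m) {
    data.frame(individual_id = m$individual_id, target = m$target,
               exposure = m$exposure,
               standard_orientation = m$standard_orientation,
               depth_m = m$depth_m, time_min = m$time_min,
               wavelength_nm = m$spectrum$wl,
               value = sprintf("%.17g", m$spectrum$value),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select a unique measurement from a list by metadata
#'
#' Convenience selector used throughout the decomposition and
#' reconstruction workflows; errors unless exactly one measurement
#' matches.
#'
#' @param measurements List of [measurement()]s.
#' @param target Target to match.
#' @param exposure,orientation,individual_id Optional additional filters.
#' @return A single [measurement()].
#' @export
find_measurement <- function(measurements, target, exposure = NULL,
                             orientation = NULL, individual_id = NULL) {
  hit <- vapply(measurements, function(m) {
    m$target == target &&
      (is.null(exposure) || m$exposure == exposure) &&
      (is.null(orientation) || m$standard_orientation == orientation) &&
      (is.null(individual_id) || m$individual_id == individual_id)
  }, logical(1))
  if (sum(hit) != 1L)
    stop(sprintf(
      "expected exactly one measurement for %s/%s (found %d)",
      target, if (is.null(exposure)) "*" else exposure, sum(hit)))
  measurements[[which(hit)]]
}
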