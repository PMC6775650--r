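#' Spectrum objects
#'
#' A `drs_spectrum` is the basic container of the package: a wavelength grid
#' in nanometres with one intensity (or reflectance) value per wavelength,
#' plus provenance: which spectrometer band it came from (`"VIS"`, `"NIR"`
#' or `"merged"`) and its processing state. States only move forward:
#' `raw -> calibrated -> stitched -> normalized`.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param value Numeric vector of intensities, same length as `wavelength`.
#' @param state Processing state, one of `"raw"`, `"calibrated"`,
#'   `"stitched"`, `"normalized"`.
#' @param band Spectrometer band of origin: `"VIS"`, `"NIR"` or `"merged"`.
#' @return An object of class `drs_spectrum`.
#' @examples
#' s <- spectrum(seq(400, 1100, by = 5), runif(141), band = "VIS")
#' @export
spectrum <- function(wavelength, value,
                     state = c("raw", "calibrated", "stitched", "normalized"),
                     band = c("merged", "VIS", "NIR")) {
  state <- match.arg(state)
  band <- match.arg(band)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value)) {
    stop("`wavelength` and `value` must have the same length", call. = FALSE)
  }
  if (length(wavelength) < 2L || any(diff(wavelength) <= 0)) {
    stop("`wavelength` must be strictly increasing with length >= 2",
         call. = FALSE)
  }
  structure(
    list(wavelength = wavelength, value = value, state = state, band = band),
    class = "drs_spectrum"
  )
}

.spectrum_states <- c(raw = 1L, calibrated = 2L, stitched = 3L, normalized = 4L)

#' @export
print.drs_spectrum <- function(x, ...) {
  cat(sprintf("<drs_spectrum> band=%s state=%s, %d points, %.0f-%.0f nm\n",
              x$band, x$state, length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

stop_if_grid_mismatch <- function(a, b, what = "spectra") {
  if (length(a$wavelength) != length(b$wavelength) ||
      any(a$wavelength != b$wavelength)) {
    stop(sprintf("%s are not on identical wavelength grids", what),
         call. = FALSE)
  }
  invisible(NULL)
}

#' Calibrate a raw spectrum against white and dark references
#'
#' Per-patient instrument response is removed with the standard
#' `(raw - dark) / (white - dark)` transform, using the white and dark
#' reference frames recorded before each patient's measurements. Values
#' driven below zero by noise (raw below dark) are clipped to 0, since
#' reflectance is physically non-negative.
#'
#' @param raw,white,dark `drs_spectrum` objects on identical grids, `raw`
#'   in state `"raw"`.
#' @return A `drs_spectrum` in state `"calibrated"`.
#' @examples
#' wl <- seq(400, 1100, by = 10)
#' white <- spectrum(wl, rep(1000, length(wl)), band = "VIS")
#' dark <- spectrum(wl, rep(50, length(wl)), band = "VIS")
#' raw <- spectrum(wl, 50 + 0.5 * 950, band = "VIS")
#' calibrate(raw, white, dark)$value[1]  # 0.5
#' @export
calibrate <- function(raw, white, dark) {
  stopifnot(inherits(raw, "drs_spectrum"), inherits(white, "drs_spectrum"),
            inherits(dark, "drs_spectrum"))
  stop_if_grid_mismatch(raw, white, "raw and white reference")
  stop_if_grid_mismatch(raw, dark, "raw and dark reference")
  denom <- white$value - dark$value
  if (any(denom <= 0)) {
    stop("degenerate references: white must exceed dark at every wavelength",
         call. = FALSE)
  }
  val <- pmax((raw$value - dark$value) / denom, 0)
  spectrum(raw$wavelength, val, state = "calibrated", band = raw$band)
}

#' Stitch the two spectrometer bands into one spectrum
#'
#' The instrument records a visible band (400--1100 nm) and a near-infrared
#' band (900--1700 nm). Both calibrated bands are interpolated onto one
#' uniform grid; in the overlap region the two are blended with a linear
#' cross-fade (the NIR weight ramps 0 to 1 across the overlap) so there is
#' no step discontinuity; outside the overlap the owning band's interpolated
#' values are used.
#'
#' @param vis,nir Calibrated `drs_spectrum` objects whose wavelength ranges
#'   overlap.
#' @param grid_step Step of the uniform merged grid in nm (default 5).
#' @return A `drs_spectrum` in state `"stitched"`, band `"merged"`, on the
#'   grid `seq(min(vis), max(nir), by = grid_step)`.
#' @export
stitch <- function(vis, nir, grid_step = 5) {
  stopifnot(inherits(vis, "drs_spectrum"), inherits(nir, "drs_spectrum"))
  for (s in list(vis, nir)) {
    if (.spectrum_states[s$state] < .spectrum_states["calibrated"]) {
      stop("both bands must be calibrated before stitching", call. = FALSE)
    }
  }
  lo <- max(min(vis$wavelength), min(nir$wavelength))
  hi <- min(max(vis$wavelength), max(nir$wavelength))
  if (lo >= hi) stop("bands do not overlap; cannot stitch", call. = FALSE)
  grid <- seq(min(vis$wavelength), max(nir$wavelength), by = grid_step)
  v <- stats::approx(vis$wavelength, vis$value, xout = grid, rule = 2)$y
  n <- stats::approx(nir$wavelength, nir$value, xout = grid, rule = 2)$y
  # NIR weight: 0 below the overlap, 1 above it, linear ramp inside
  w <- pmin(pmax((grid - lo) / (hi - lo), 0), 1)
  out <- ifelse(grid < lo, v, ifelse(grid > hi, n, (1 - w) * v + w * n))
  spectrum(grid, out, state = "stitched", band = "merged")
}

#' Normalize a spectrum at 800 nm
#'
#' Divides all values by the value at 800 nm, obtained by linear
#' interpolation between the neighbouring grid points (the grid need not
#' contain 800 nm exactly). After the operation the value at 800 nm is 1;
#' the operation is idempotent and invariant under rescaling of the input.
#'
#' @param s A stitched (or already normalized) `drs_spectrum` covering
#'   800 nm.
#' @return A `drs_spectrum` in state `"normalized"`.
#' @export
normalize_at_800 <- function(s) {
  stopifnot(inherits(s, "drs_spectrum"))
  if (.spectrum_states[s$state] < .spectrum_states["stitched"]) {
    stop("spectrum must be stitched before normalization", call. = FALSE)
  }
  if (min(s$wavelength) > 800 || max(s$wavelength) < 800) {
    stop("spectrum does not cover 800 nm", call. = FALSE)
  }
  ref <- stats::approx(s$wavelength, s$value, xout = 800)$y
  if (!is.finite(ref) || ref <= 0) {
    stop("value at 800 nm is not positive; cannot normalize", call. = FALSE)
  }
  spectrum(s$wavelength, s$value / ref, state = "normalized", band = s$band)
}
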