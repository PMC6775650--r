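#' Optical property set of a tissue
#'
#' The latent parameters from which the simulator builds a reflectance
#' spectrum: a reduced-scattering power law and the volume fractions of the
#' dominant soft-tissue chromophores (whole blood with its oxygen
#' saturation, water, lipid).
#'
#' @param scatter_amplitude Reduced scattering coefficient at the 800 nm
#'   reference wavelength, in 1/mm; must be > 0.
#' @param scatter_power Dimensionless scattering power `b` in
#'   `mu_s'(lambda) = a * (lambda/800)^-b`.
#' @param blood_fraction,oxygen_saturation,water_fraction,fat_fraction
#'   Volume fractions in `[0, 1]` (`oxygen_saturation` is the oxygenated
#'   fraction of the blood).
#' @return An object of class `optical_properties`.
#' @export
optical_properties <- function(scatter_amplitude, scatter_power,
                               blood_fraction, oxygen_saturation,
                               water_fraction, fat_fraction) {
  p <- list(scatter_amplitude = scatter_amplitude,
            scatter_power = scatter_power,
            blood_fraction = blood_fraction,
            oxygen_saturation = oxygen_saturation,
            water_fraction = water_fraction,
            fat_fraction = fat_fraction)
  if (any(!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1)))) {
    stop("all optical properties must be finite scalars", call. = FALSE)
  }
  if (p$scatter_amplitude <= 0) {
    stop("scatter_amplitude must be > 0", call. = FALSE)
  }
  fr <- c(p$blood_fraction, p$oxygen_saturation, p$water_fraction,
          p$fat_fraction)
  if (any(fr < 0 | fr > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "optical_properties")
}

# Pseudo-chromophore absorption bands: Gaussian stand-ins for the literature
# extinction spectra, so the simulator needs no external data tables.
# Each row: amplitude of mu_a in 1/mm at unit chromophore fraction,
# band center (nm), band width (Gaussian sd, nm). Centers follow the
# well-known features: Soret and alpha/beta hemoglobin bands in the visible,
# the deoxy-hemoglobin 760 nm band, lipid near 930/1210 nm and water near
# 970/1180/1450 nm.
.chromophore_bands <- list(
  oxy_hb = cbind(amplitude = c(60, 18, 17),
                 center    = c(415, 542, 577),
                 width     = c(18, 12, 10)),
  deoxy_hb = cbind(amplitude = c(55, 20, 1.6),
                   center    = c(432, 556, 758),
                   width     = c(20, 16, 28)),
  water = cbind(amplitude = c(0.06, 0.10, 2.80),
                center    = c(970, 1190, 1450),
                width     = c(28, 40, 55)),
  fat = cbind(amplitude = c(0.035, 0.65, 0.30),
              center    = c(928, 1210, 1395),
              width     = c(18, 28, 45))
)

gaussian_band_sum <- function(wavelength, bands) {
  out <- numeric(length(wavelength))
  for (i in seq_len(nrow(bands))) {
    out <- out + unname(bands[i, "amplitude"]) *
      exp(-0.5 * ((wavelength - unname(bands[i, "center"])) /
                    unname(bands[i, "width"]))^2)
  }
  out
}

#' Absorption coefficient spectrum from chromophore fractions
#'
#' Builds `mu_a(lambda)` in 1/mm as a linear combination of fixed Gaussian
#' pseudo-chromophore bands weighted by the tissue's chromophore fractions:
#' blood (split into oxy- and deoxy-hemoglobin by the oxygen saturation),
#' water and lipid. Linear in every concentration; non-negative everywhere.
#'
#' @param wavelength Wavelengths in nm, all within \[400, 1700\].
#' @param props An [optical_properties] object.
#' @return Numeric vector of absorption coefficients (1/mm).
#' @export
chromophore_absorption <- function(wavelength, props) {
  stopifnot(inherits(props, "optical_properties"))
  if (any(wavelength < 400 | wavelength > 1700)) {
    stop("wavelengths must lie within [400, 1700] nm", call. = FALSE)
  }
  b <- .chromophore_bands
  hb <- props$oxygen_saturation * gaussian_band_sum(wavelength, b$oxy_hb) +
    (1 - props$oxygen_saturation) * gaussian_band_sum(wavelength, b$deoxy_hb)
  props$blood_fraction * hb +
    props$water_fraction * gaussian_band_sum(wavelength, b$water) +
    props$fat_fraction * gaussian_band_sum(wavelength, b$fat)
}

#' Reduced scattering spectrum from the power law
#'
#' `mu_s'(lambda) = scatter_amplitude * (lambda / 800)^-scatter_power`,
#' the usual wavelength power law with its amplitude referenced at 800 nm.
#'
#' @inheritParams chromophore_absorption
#' @return Numeric vector of reduced scattering coefficients (1/mm).
#' @export
reduced_scattering <- function(wavelength, props) {
  stopifnot(inherits(props, "optical_properties"))
  props$scatter_amplitude * (wavelength / 800)^(-props$scatter_power)
}

# Internal reflection parameter for tissue/probe refractive index n = 1.4
# (Groenhuis empirical fit for the effective reflection coefficient).
.diffusion_A <- local({
  n <- 1.4
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + rd) / (1 - rd)
})

#' Diffuse reflectance at a fixed source-detector separation
#'
#' Steady-state diffusion-approximation reflectance of a semi-infinite
#' homogeneous medium for a point source, evaluated at radial distance
#' `separation` from the source (the fiber separation of the probe). This is
#' the classic two-dipole (source + image source across the extrapolated
#' boundary) closed form with an internal-reflection boundary for refractive
#' index 1.4. Strictly positive, and strictly decreasing in `mu_a` at fixed
#' `mu_s_prime`.
#'
#' @param mu_a Absorption coefficient spectrum, 1/mm, `>= 0`.
#' @param mu_s_prime Reduced scattering coefficient spectrum, 1/mm, `> 0`.
#' @param separation Source-detector separation in mm (default 1.29, the
#'   probe geometry).
#' @return Numeric vector of reflectance values (1/mm^2 sr-free units; only
#'   relative shape matters downstream).
#' @export
reflectance <- function(mu_a, mu_s_prime, separation = 1.29) {
  if (length(mu_a) != length(mu_s_prime)) {
    stop("mu_a and mu_s_prime must have the same length", call. = FALSE)
  }
  if (any(mu_a < 0)) stop("mu_a must be non-negative", call. = FALSE)
  if (any(mu_s_prime <= 0)) {
    stop("mu_s_prime must be strictly positive", call. = FALSE)
  }
  if (separation <= 0) stop("separation must be > 0", call. = FALSE)
  mu_t <- mu_a + mu_s_prime
  z0 <- 1 / mu_t
  zb <- 2 * .diffusion_A / (3 * mu_t)
  mu_eff <- sqrt(3 * mu_a * mu_t)
  r1 <- sqrt(z0^2 + separation^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + separation^2)
  (z0 * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / r1^2 +
     (z0 + 2 * zb) * (mu_eff + 1 / r2) * exp(-mu_eff * r2) / r2^2) / (4 * pi)
}

#' Mix a surface-tissue and a buried-tumor reflectance spectrum
#'
#' A buried tumor under a layer of healthy wall contributes less to the
#' measured spectrum the deeper it starts. The measured spectrum is modeled
#' as the convex combination `w * tumor + (1 - w) * surface` with
#' `w = exp(-depth_mm / sensing_depth_mm)`: at depth 0 the pure tumor
#' spectrum, decaying toward the surface-tissue spectrum on the scale of the
#' probe's sensing depth (approximately the 1.29 mm fiber separation).
#'
#' @param surface_spectrum,tumor_spectrum Numeric vectors on the same grid.
#' @param depth_mm Depth from the measurement surface to the first tumor
#'   tissue, mm, `>= 0`.
#' @param sensing_depth_mm Exponential mixing scale in mm (default 1.29).
#' @return Numeric vector between the two inputs element-wise.
#' @export
two_layer_mix <- function(surface_spectrum, tumor_spectrum, depth_mm,
                          sensing_depth_mm = 1.29) {
  if (length(surface_spectrum) != length(tumor_spectrum)) {
    stop("surface and tumor spectra must be on the same grid", call. = FALSE)
  }
  if (depth_mm < 0) stop("depth_mm must be >= 0", call. = FALSE)
  if (sensing_depth_mm <= 0) {
    stop("sensing_depth_mm must be > 0", call. = FALSE)
  }
  w <- exp(-depth_mm / sensing_depth_mm)
  w * tumor_spectrum + (1 - w) * surface_spectrum
}
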