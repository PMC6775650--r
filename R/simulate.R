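#' Tissue class model: distribution of optical properties for one class
#'
#' @param class_name One of `"fat"`, `"wall"`, `"tumor"`.
#' @param means An [optical_properties] object with the class means.
#' @param sds An [optical_properties]-shaped named list of component-wise
#'   standard deviations (all `>= 0`). Sampled properties are clipped back
#'   to their valid ranges.
#' @return An object of class `tissue_class_model`.
#' @export
tissue_class_model <- function(class_name = c("fat", "wall", "tumor"),
                               means, sds) {
  class_name <- match.arg(class_name)
  stopifnot(inherits(means, "optical_properties"))
  fields <- names(unclass(means))
  sds <- unlist(sds)[fields]
  if (any(is.na(sds)) || any(sds < 0)) {
    stop("sds must be named, complete and non-negative", call. = FALSE)
  }
  structure(list(class_name = class_name, means = means, sds = sds),
            class = "tissue_class_model")
}

#' Default tissue class models
#'
#' Plausible optical-property distributions for peritumoral fat, healthy
#' colorectal wall and colorectal tumor over 400--1700 nm: fat is
#' lipid-dominated with a flat scattering slope; wall is water-dominated
#' muscle-like tissue with modest blood content; tumor has elevated blood
#' content, reduced oxygen saturation and denser scattering. The contrasts
#' (blood, saturation, water/lipid balance, scattering slope) are the ones
#' the discrimination task rests on in vivo.
#'
#' @param separation_scale Multiplier on the distance of each class mean
#'   from the across-class average (1 = defaults). Used to study how class
#'   separability drives downstream accuracy.
#' @return Named list of three [tissue_class_model] objects.
#' @export
default_tissue_models <- function(separation_scale = 1) {
  mk <- function(name, a, b, bl, s, w, f, sds) {
    tissue_class_model(name, optical_properties(a, b, bl, s, w, f), sds)
  }
  base <- list(
    fat = mk("fat", 1.60, 0.45, 0.004, 0.80, 0.15, 0.70,
             c(scatter_amplitude = 0.20, scatter_power = 0.10,
               blood_fraction = 0.002, oxygen_saturation = 0.05,
               water_fraction = 0.05, fat_fraction = 0.08)),
    wall = mk("wall", 0.85, 1.20, 0.010, 0.75, 0.70, 0.05,
              c(scatter_amplitude = 0.12, scatter_power = 0.15,
                blood_fraction = 0.004, oxygen_saturation = 0.08,
                water_fraction = 0.06, fat_fraction = 0.03)),
    tumor = mk("tumor", 1.30, 1.50, 0.030, 0.55, 0.78, 0.02,
               c(scatter_amplitude = 0.16, scatter_power = 0.18,
                 blood_fraction = 0.010, oxygen_saturation = 0.10,
                 water_fraction = 0.06, fat_fraction = 0.015))
  )
  if (separation_scale != 1) {
    fields <- names(unclass(base$fat$means))
    m <- sapply(base, function(cl) unlist(unclass(cl$means)))
    center <- rowMeans(m)
    for (nm in names(base)) {
      shifted <- center + separation_scale * (m[, nm] - center)
      shifted <- clip_properties(shifted)
      base[[nm]]$means <- do.call(optical_properties, as.list(shifted[fields]))
    }
  }
  base
}

clip_properties <- function(p) {
  p["scatter_amplitude"] <- max(p["scatter_amplitude"], 1e-3)
  for (nm in c("blood_fraction", "oxygen_saturation", "water_fraction",
               "fat_fraction")) {
    p[nm] <- min(max(p[nm], 0), 1)
  }
  p
}

sample_properties <- function(model) {
  m <- unlist(unclass(model$means))
  p <- m + stats::rnorm(length(m), 0, model$sds[names(m)])
  p <- clip_properties(p)
  do.call(optical_properties, as.list(p))
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: cohort size and
#' per-patient sampling plan, probe geometry and spectrometer bands,
#' measurement noise, the buried-tumor depth distribution, the rate of
#' inconclusive histopathology among tumor sites, and how often (and how
#' well) the surgeon judges each site.
#'
#' @param n_patients Number of patients (default 32).
#' @param locations_per_patient Named counts of measured locations per
#'   patient for `fat`, `wall`, `tumor` (default 4/3/2; with 3 replicate
#'   spectra each this emulates the study's 402/282/151 class imbalance).
#' @param replicates_per_location Replicate spectra per location (default 3).
#' @param fiber_separation_mm Source-detector separation (default 1.29 mm),
#'   also the sensing-depth scale of the buried-tumor mixing.
#' @param vis_band,nir_band Wavelength ranges (nm) of the two spectrometers.
#' @param grid_step_nm Step of the raw per-band grids and of the merged grid.
#' @param noise_sd Relative (multiplicative) Gaussian noise on each recorded
#'   intensity.
#' @param depth_p_surface Probability that a tumor location has tumor at the
#'   surface (depth 0).
#' @param depth_mean_mm Mean of the exponential depth tail for buried tumors.
#' @param depth_max_mm Truncation of the depth tail.
#' @param inconclusive_fraction Fraction of tumor locations whose lateral
#'   tumor extent is below 0.5 mm, i.e. histopathology correlation is
#'   inconclusive (default 0.38, the study's exclusion rate).
#' @param surgeon_uncertain_fraction Fraction of locations on which the
#'   surgeon is uncertain (default 0.2, echoing 54 of 270 locations).
#' @param surgeon_correct_rate_certain Probability the surgeon's binary call
#'   is correct on locations judged with certainty.
#' @param surgeon_fp_rate_on_uncertain Probability the surgeon calls a truly
#'   healthy, uncertain location tumor (default 0.69).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 32,
                       locations_per_patient = c(fat = 4, wall = 3, tumor = 2),
                       replicates_per_location = 3,
                       fiber_separation_mm = 1.29,
                       vis_band = c(400, 1100),
                       nir_band = c(900, 1700),
                       grid_step_nm = 5,
                       noise_sd = 0.01,
                       depth_p_surface = 0.30,
                       depth_mean_mm = 1.5,
                       depth_max_mm = 6,
                       inconclusive_fraction = 0.38,
                       surgeon_uncertain_fraction = 0.2,
                       surgeon_correct_rate_certain = 0.97,
                       surgeon_fp_rate_on_uncertain = 0.69,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              locations_per_patient = locations_per_patient,
              replicates_per_location = as.integer(replicates_per_location),
              fiber_separation_mm = fiber_separation_mm,
              vis_band = vis_band, nir_band = nir_band,
              grid_step_nm = grid_step_nm, noise_sd = noise_sd,
              depth_p_surface = depth_p_surface,
              depth_mean_mm = depth_mean_mm, depth_max_mm = depth_max_mm,
              inconclusive_fraction = inconclusive_fraction,
              surgeon_uncertain_fraction = surgeon_uncertain_fraction,
              surgeon_correct_rate_certain = surgeon_correct_rate_certain,
              surgeon_fp_rate_on_uncertain = surgeon_fp_rate_on_uncertain,
              seed = as.integer(seed))
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (!all(c("fat", "wall", "tumor") %in% names(cfg$locations_per_patient))) {
    stop("locations_per_patient needs named counts for fat, wall, tumor",
         call. = FALSE)
  }
  if (cfg$replicates_per_location < 1L) {
    stop("replicates_per_location must be >= 1", call. = FALSE)
  }
  fracs <- c(noise_sd = cfg$noise_sd >= 0,
             depth_p_surface = cfg$depth_p_surface >= 0 &&
               cfg$depth_p_surface <= 1,
             inconclusive_fraction = cfg$inconclusive_fraction >= 0 &&
               cfg$inconclusive_fraction <= 1,
             surgeon_uncertain_fraction =
               cfg$surgeon_uncertain_fraction >= 0 &&
               cfg$surgeon_uncertain_fraction <= 1,
             surgeon_correct_rate_certain =
               cfg$surgeon_correct_rate_certain >= 0 &&
               cfg$surgeon_correct_rate_certain <= 1,
             surgeon_fp_rate_on_uncertain =
               cfg$surgeon_fp_rate_on_uncertain >= 0 &&
               cfg$surgeon_fp_rate_on_uncertain <= 1)
  if (!all(fracs)) {
    stop("invalid configuration field(s): ",
         paste(names(fracs)[!fracs], collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

band_grid <- function(band, step) seq(band[1], band[2], by = step)

# Smooth lamp x detector response shape for a white reference, in counts.
white_shape <- function(wavelength, gain) {
  gain * 4e4 * exp(-0.5 * ((wavelength - 1050) / 420)^2) + 2000
}

#' Simulate a full DRS dataset
#'
#' Generates, deterministically for a given configuration, a cohort of
#' patients each with fat, wall and tumor measurement locations. For each
#' location optical properties are drawn from its class model, converted to
#' a diffusion-model reflectance spectrum; buried tumors are mixed with an
#' overlying healthy-wall spectrum according to their depth. Each replicate
#' spectrum is then rendered as raw two-band intensity frames
#' (`reflectance x (white - dark) + dark` plus relative Gaussian noise)
#' against per-patient white/dark reference frames. Surgeon judgement and
#' certainty labels and inconclusive-histopathology extents are attached
#' per location.
#'
#' @param config A [sim_config].
#' @param models Tissue class models, as from [default_tissue_models()].
#' @return An object of class `drs_dataset`: a list with `locations` and
#'   `measurements` data frames, raw intensity matrices `raw_vis` and
#'   `raw_nir` (one row per measurement), per-band wavelength grids, and
#'   per-patient `references` (white/dark frames for each band).
#' @export
simulate_dataset <- function(config = sim_config(),
                             models = default_tissue_models()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  wl_vis <- band_grid(config$vis_band, config$grid_step_nm)
  wl_nir <- band_grid(config$nir_band, config$grid_step_nm)
  wl_all <- sort(unique(c(wl_vis, wl_nir)))
  i_vis <- match(wl_vis, wl_all)
  i_nir <- match(wl_nir, wl_all)

  classes <- c("fat", "wall", "tumor")
  n_per <- config$locations_per_patient[classes]
  n_loc <- config$n_patients * sum(n_per)
  n_rep <- config$replicates_per_location

  references <- list()
  loc_rows <- vector("list", n_loc)
  refl <- matrix(NA_real_, n_loc, length(wl_all))
  li <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    gain_vis <- stats::runif(1, 0.85, 1.15)
    gain_nir <- stats::runif(1, 0.85, 1.15)
    dark_vis <- stats::rnorm(length(wl_vis), 500, 2) + stats::runif(1, -30, 30)
    dark_nir <- stats::rnorm(length(wl_nir), 700, 2) + stats::runif(1, -30, 30)
    references[[pid]] <- list(
      white_vis = white_shape(wl_vis, gain_vis), dark_vis = dark_vis,
      white_nir = white_shape(wl_nir, gain_nir), dark_nir = dark_nir)
    for (cls in classes) {
      for (j in seq_len(n_per[[cls]])) {
        li <- li + 1L
        props <- sample_properties(models[[cls]])
        mu_a <- chromophore_absorption(wl_all, props)
        mu_s <- reduced_scattering(wl_all, props)
        r <- reflectance(mu_a, mu_s, config$fiber_separation_mm)
        depth <- NA_real_
        extent <- NA_real_
        if (cls == "tumor") {
          depth <- if (stats::runif(1) < config$depth_p_surface) 0 else
            min(stats::rexp(1, 1 / config$depth_mean_mm), config$depth_max_mm)
          extent <- if (stats::runif(1) < config$inconclusive_fraction)
            stats::runif(1, 0.05, 0.45) else stats::runif(1, 1, 15)
          wall_props <- sample_properties(models[["wall"]])
          wall_r <- reflectance(chromophore_absorption(wl_all, wall_props),
                                reduced_scattering(wl_all, wall_props),
                                config$fiber_separation_mm)
          r <- two_layer_mix(wall_r, r, depth, config$fiber_separation_mm)
        }
        refl[li, ] <- r
        truth_binary <- if (cls == "tumor") "tumor" else "healthy"
        uncertain <- stats::runif(1) < config$surgeon_uncertain_fraction
        surgeon <- if (uncertain) {
          if (cls == "tumor") "tumor" else {
            if (stats::runif(1) < config$surgeon_fp_rate_on_uncertain)
              "tumor" else "healthy"
          }
        } else {
          if (stats::runif(1) < config$surgeon_correct_rate_certain)
            truth_binary else setdiff(c("healthy", "tumor"), truth_binary)
        }
        loc_rows[[li]] <- data.frame(
          location_id = sprintf("L%03d", li), patient_id = pid,
          true_class = cls, tumor_depth_mm = depth, tumor_extent_mm = extent,
          surgeon_class = surgeon, surgeon_certain = !uncertain,
          stringsAsFactors = FALSE)
      }
    }
  }
  locations <- do.call(rbind, loc_rows)

  n_meas <- n_loc * n_rep
  raw_vis <- matrix(NA_real_, n_meas, length(wl_vis))
  raw_nir <- matrix(NA_real_, n_meas, length(wl_nir))
  measurements <- data.frame(
    measurement_id = sprintf("M%04d", seq_len(n_meas)),
    location_id = rep(locations$location_id, each = n_rep),
    patient_id = rep(locations$patient_id, each = n_rep),
    replicate = rep(seq_len(n_rep), times = n_loc),
    stringsAsFactors = FALSE)
  for (li in seq_len(n_loc)) {
    ref <- references[[locations$patient_id[li]]]
    for (k in seq_len(n_rep)) {
      mi <- (li - 1L) * n_rep + k
      rv <- refl[li, i_vis]
      rn <- refl[li, i_nir]
      if (config$noise_sd > 0) {
        rv <- rv * (1 + stats::rnorm(length(rv), 0, config$noise_sd))
        rn <- rn * (1 + stats::rnorm(length(rn), 0, config$noise_sd))
      }
      # reflectance shapes scaled into detector counts between dark and white
      sc <- 0.9 / max(refl[li, ])
      raw_vis[mi, ] <- ref$dark_vis + (ref$white_vis - ref$dark_vis) * sc * rv
      raw_nir[mi, ] <- ref$dark_nir + (ref$white_nir - ref$dark_nir) * sc * rn
    }
  }
  structure(list(config = config, locations = locations,
                 measurements = measurements,
                 wl_vis = wl_vis, wl_nir = wl_nir,
                 raw_vis = raw_vis, raw_nir = raw_nir,
                 references = references),
            class = "drs_dataset")
}

#' @export
print.drs_dataset <- function(x, ...) {
  cat(sprintf(
    "<drs_dataset> %d patients, %d locations (%s), %d spectra x 2 bands\n",
    length(unique(x$locations$patient_id)), nrow(x$locations),
    paste(sprintf("%s=%d", names(table(x$locations$true_class)),
                  table(x$locations$true_class)), collapse = ", "),
    nrow(x$measurements)))
  invisible(x)
}

#' Preprocess a dataset into the classifier feature matrix
#'
#' Runs the full preprocessing chain on every measurement: white/dark
#' calibration per band against the patient's reference frames, stitching
#' of the two bands onto the uniform merged grid, and normalization at
#' 800 nm. Rows are measurements, columns the merged wavelength grid.
#'
#' @param dataset A `drs_dataset`.
#' @param grid_step Merged grid step in nm (defaults to the dataset's).
#' @return List with `features` (matrix, one row per measurement),
#'   `wavelength` (merged grid), and the dataset's `measurements` table.
#' @export
preprocess_dataset <- function(dataset, grid_step = NULL) {
  stopifnot(inherits(dataset, "drs_dataset"))
  if (is.null(grid_step)) grid_step <- dataset$config$grid_step_nm
  n <- nrow(dataset$measurements)
  first <- TRUE
  features <- NULL
  grid <- NULL
  for (i in seq_len(n)) {
    ref <- dataset$references[[dataset$measurements$patient_id[i]]]
    vis <- calibrate(
      spectrum(dataset$wl_vis, dataset$raw_vis[i, ], "raw", "VIS"),
      spectrum(dataset$wl_vis, ref$white_vis, "raw", "VIS"),
      spectrum(dataset$wl_vis, ref$dark_vis, "raw", "VIS"))
    nir <- calibrate(
      spectrum(dataset$wl_nir, dataset$raw_nir[i, ], "raw", "NIR"),
      spectrum(dataset$wl_nir, ref$white_nir, "raw", "NIR"),
      spectrum(dataset$wl_nir, ref$dark_nir, "raw", "NIR"))
    s <- normalize_at_800(stitch(vis, nir, grid_step))
    if (first) {
      grid <- s$wavelength
      features <- matrix(NA_real_, n, length(grid))
      first <- FALSE
    }
    features[i, ] <- s$value
  }
  colnames(features) <- sprintf("wl_%g", grid)
  rownames(features) <- dataset$measurements$measurement_id
  list(features = features, wavelength = grid,
       measurements = dataset$measurements)
}
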