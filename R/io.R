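#' Write a dataset to plain-text files
#'
#' Writes the CSV dialect of the package: `spectra.csv` (one row per
#' measurement x band x wavelength: measurement id, location id, replicate,
#' band, wavelength_nm, intensity), `metadata.csv` (one row per location
#' with patient, class, depth, extent and surgeon fields),
#' `references.csv` (per patient and band: wavelength, white, dark) and
#' `config.yaml` mirroring the [sim_config] field for field.
#'
#' @param dataset A `drs_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "drs_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- dataset$measurements
  spectra <- rbind(
    data.frame(measurement_id = rep(m$measurement_id,
                                    each = length(dataset$wl_vis)),
               location_id = rep(m$location_id, each = length(dataset$wl_vis)),
               replicate = rep(m$replicate, each = length(dataset$wl_vis)),
               band = "VIS",
               wavelength_nm = rep(dataset$wl_vis, times = nrow(m)),
               intensity = as.vector(t(dataset$raw_vis))),
    data.frame(measurement_id = rep(m$measurement_id,
                                    each = length(dataset$wl_nir)),
               location_id = rep(m$location_id, each = length(dataset$wl_nir)),
               replicate = rep(m$replicate, each = length(dataset$wl_nir)),
               band = "NIR",
               wavelength_nm = rep(dataset$wl_nir, times = nrow(m)),
               intensity = as.vector(t(dataset$raw_nir))))
  utils::write.csv(spectra, file.path(dir, "spectra.csv"), row.names = FALSE)
  utils::write.csv(dataset$locations, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  refs <- do.call(rbind, lapply(names(dataset$references), function(pid) {
    r <- dataset$references[[pid]]
    rbind(data.frame(patient_id = pid, band = "VIS",
                     wavelength_nm = dataset$wl_vis,
                     white = r$white_vis, dark = r$dark_vis),
          data.frame(patient_id = pid, band = "NIR",
                     wavelength_nm = dataset$wl_nir,
                     white = r$white_nir, dark = r$dark_nir))
  }))
  utils::write.csv(refs, file.path(dir, "references.csv"), row.names = FALSE)
  cfg <- unclass(dataset$config)
  # yaml drops names of atomic vectors; keep the class counts as a map
  cfg$locations_per_patient <- as.list(cfg$locations_per_patient)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  spectra <- utils::read.csv(file.path(dir, "spectra.csv"),
                             stringsAsFactors = FALSE)
  locations <- utils::read.csv(file.path(dir, "metadata.csv"),
                               stringsAsFactors = FALSE)
  refs <- utils::read.csv(file.path(dir, "references.csv"),
                          stringsAsFactors = FALSE)
  config <- read_sim_config(file.path(dir, "config.yaml"))
  wl_vis <- sort(unique(spectra$wavelength_nm[spectra$band == "VIS"]))
  wl_nir <- sort(unique(spectra$wavelength_nm[spectra$band == "NIR"]))
  vis <- spectra[spectra$band == "VIS", ]
  nir <- spectra[spectra$band == "NIR", ]
  ids <- unique(spectra$measurement_id)
  vis <- vis[order(match(vis$measurement_id, ids), vis$wavelength_nm), ]
  nir <- nir[order(match(nir$measurement_id, ids), nir$wavelength_nm), ]
  raw_vis <- matrix(vis$intensity, nrow = length(ids), byrow = TRUE)
  raw_nir <- matrix(nir$intensity, nrow = length(ids), byrow = TRUE)
  first <- !duplicated(spectra$measurement_id)
  measurements <- data.frame(
    measurement_id = ids,
    location_id = spectra$location_id[first],
    patient_id = locations$patient_id[match(spectra$location_id[first],
                                            locations$location_id)],
    replicate = spectra$replicate[first], stringsAsFactors = FALSE)
  references <- lapply(split(refs, refs$patient_id), function(r) {
    rv <- r[r$band == "VIS", ]
    rn <- r[r$band == "NIR", ]
    rv <- rv[order(rv$wavelength_nm), ]
    rn <- rn[order(rn$wavelength_nm), ]
    list(white_vis = rv$white, dark_vis = rv$dark,
         white_nir = rn$white, dark_nir = rn$dark)
  })
  structure(list(config = config, locations = locations,
                 measurements = measurements, wl_vis = wl_vis,
                 wl_nir = wl_nir, raw_vis = raw_vis, raw_nir = raw_nir,
                 references = references),
            class = "drs_dataset")
}

#' Read a simulation configuration from YAML or JSON
#'
#' The document mirrors [sim_config] field for field; unknown fields are an
#' error naming the field, as is any missing or out-of-range value.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [sim_config].
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(sim_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown configuration field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$locations_per_patient)) {
    raw$locations_per_patient <- unlist(raw$locations_per_patient)
  }
  do.call(sim_config, raw)
}

log_msg <- function(...) message(sprintf(...))

#' Generate a dataset and write it to disk
#'
#' @param config A [sim_config], or a path to a YAML/JSON configuration.
#' @param out_dir Output directory.
#' @param seed Optional seed overriding the configuration's.
#' @return The generated `drs_dataset`, invisibly.
#' @export
run_simulate <- function(config = sim_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_sim_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dataset <- simulate_dataset(config)
  log_msg("simulate: seed=%d patients=%d locations=%d spectra=%d",
          config$seed, config$n_patients, nrow(dataset$locations),
          nrow(dataset$measurements))
  write_dataset(dataset, out_dir)
  invisible(dataset)
}

#' Run the full classification workflow
#'
#' Preprocesses every spectrum (calibration, stitching, 800 nm
#' normalization), applies the depth rule to derive classification labels
#' (dropping inconclusive locations), runs the repeated ten-fold
#' cross-validated cascade, and writes `report.json` (per-class metrics
#' mean and SD at measurement and location level, weighted accuracy),
#' `predictions.csv` (one row per out-of-fold prediction record) and
#' `roc_<class>.csv` curves. Logged to stderr: seed, row counts in and out
#' of every filter, and the number of inconclusive locations excluded.
#'
#' @param input A `drs_dataset` or a directory written by [write_dataset()].
#' @param out_dir Output directory.
#' @param rule [depth_rule] used for labeling.
#' @param k,repeats,seed,cost,group_by_patient Cross-validation settings.
#' @return List with `report` (measurement level), `report_location`,
#'   `predictions`, invisibly.
#' @export
run_pipeline <- function(input, out_dir = NULL, rule = depth_rule(),
                         k = 10, repeats = 10, seed = 1L, cost = 1,
                         group_by_patient = FALSE) {
  dataset <- if (is.character(input)) read_dataset(input) else input
  stopifnot(inherits(dataset, "drs_dataset"))
  missing_ref <- setdiff(dataset$measurements$patient_id,
                         names(dataset$references))
  if (length(missing_ref)) {
    stop("missing reference frames for patient(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  features <- preprocess_dataset(dataset)
  rl <- rule_labels(dataset$locations, rule)
  n_excluded <- sum(!rl$keep)
  keep_loc <- dataset$locations$location_id[rl$keep]
  sel <- dataset$measurements$location_id %in% keep_loc
  log_msg(paste0("run: seed=%d spectra_in=%d locations_in=%d ",
                 "excluded_inconclusive_locations=%d spectra_kept=%d"),
          seed, nrow(dataset$measurements), nrow(dataset$locations),
          n_excluded, sum(sel))
  meas <- dataset$measurements[sel, , drop = FALSE]
  lab <- rl$labels[rl$keep][match(meas$location_id, keep_loc)]
  predictions <- cross_validate(features$features[sel, , drop = FALSE],
                                meas, lab, k = k, repeats = repeats,
                                seed = seed, cost = cost,
                                group_by_patient = group_by_patient)
  report <- metrics_report(predictions, level = "measurement")
  report_loc <- metrics_report(predictions, level = "location")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, k = k, repeats = repeats,
           n_excluded_inconclusive = n_excluded,
           measurement_level = list(per_class = report$per_class,
                                    weighted_accuracy =
                                      report$weighted_accuracy),
           location_level = list(per_class = report_loc$per_class,
                                 weighted_accuracy =
                                   report_loc$weighted_accuracy)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    for (cl in names(report$roc)) {
      utils::write.csv(report$roc[[cl]]$points,
                       file.path(out_dir, sprintf("roc_%s.csv", cl)),
                       row.names = FALSE)
    }
  }
  invisible(list(report = report, report_location = report_loc,
                 predictions = predictions))
}

#' Run the depth sweep and write the sweep table
#'
#' @inheritParams run_pipeline
#' @param depths Maximum-depth grid, mm.
#' @return The sweep data frame, invisibly.
#' @export
run_depth_sweep <- function(input, out_dir = NULL,
                            depths = c(0, 1, 1.5, 2, 3, 4, Inf),
                            k = 10, repeats = 10, seed = 1L, cost = 1) {
  dataset <- if (is.character(input)) read_dataset(input) else input
  sweep <- depth_sweep(dataset, depths = depths, k = k, repeats = repeats,
                       seed = seed, cost = cost)
  log_msg("depth-sweep: seed=%d depths=%s", seed,
          paste(depths, collapse = ","))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sweep, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
  }
  invisible(sweep)
}

#' Run the surgeon-comparison analysis and write its tables
#'
#' Writes `comparison.json` with both confusion tables, the calibrated
#' threshold and the false-positive rates, plus a formatted text rendering.
#'
#' @inheritParams run_pipeline
#' @return The comparison list, invisibly.
#' @export
run_compare_surgeon <- function(input, out_dir = NULL, rule = depth_rule(),
                                k = 10, repeats = 10, seed = 1L, cost = 1) {
  dataset <- if (is.character(input)) read_dataset(input) else input
  cmp <- compare_with_surgeon(dataset, rule = rule, k = k,
                              repeats = repeats, seed = seed, cost = cost)
  log_msg("compare-surgeon: seed=%d certain=%d uncertain=%d threshold=%.4f",
          seed, cmp$n_certain, cmp$n_uncertain, cmp$calibration$threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(threshold = cmp$calibration$threshold,
           n_certain = cmp$n_certain, n_uncertain = cmp$n_uncertain,
           classifier = unclass(cmp$classifier),
           surgeon = unclass(cmp$surgeon),
           classifier_fp_rate = cmp$classifier_fp_rate,
           surgeon_fp_rate = cmp$surgeon_fp_rate,
           classifier_sensitivity = cmp$classifier_sensitivity,
           classifier_specificity = cmp$classifier_specificity),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
    txt <- c(
      "Uncertain locations: histopathology vs surgeon and classifier",
      sprintf("  surgeon    : healthy-truth %d healthy / %d tumor (FP %.0f%%)",
              cmp$surgeon$TN, cmp$surgeon$FP, 100 * cmp$surgeon_fp_rate),
      sprintf("               tumor-truth   %d healthy / %d tumor",
              cmp$surgeon$FN, cmp$surgeon$TP),
      sprintf("  classifier : healthy-truth %d healthy / %d tumor (FP %.0f%%)",
              cmp$classifier$TN, cmp$classifier$FP,
              100 * cmp$classifier_fp_rate),
      sprintf("               tumor-truth   %d healthy / %d tumor",
              cmp$classifier$FN, cmp$classifier$TP))
    writeLines(txt, file.path(out_dir, "comparison.txt"))
  }
  invisible(cmp)
}
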