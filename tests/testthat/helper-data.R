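# Small fixtures shared across tests; everything is generated in code.

# Coarse-grid, few-patient configuration for fast end-to-end tests.
tiny_config <- function(seed = 42L, n_patients = 6, ...) {
  sim_config(n_patients = n_patients,
             locations_per_patient = c(fat = 2, wall = 2, tumor = 2),
             grid_step_nm = 20, seed = seed, ...)
}

# Two well-separated Gaussian point clouds per class in a low-dimensional
# feature space, for cascade unit tests that need no optics.
gaussian_classes <- function(n_per_class = 30, d = 8, sep = 6, seed = 1) {
  set.seed(seed)
  centers <- list(fat = c(sep, 0, rep(0, d - 2)),
                  wall = c(0, 0, rep(0, d - 2)),
                  tumor = c(0, sep, rep(0, d - 2)))
  x <- do.call(rbind, lapply(centers, function(mu)
    sweep(matrix(rnorm(n_per_class * d), n_per_class, d), 2, mu, `+`)))
  colnames(x) <- sprintf("f%d", seq_len(d))
  labels <- rep(names(centers), each = n_per_class)
  meas <- data.frame(
    measurement_id = sprintf("M%03d", seq_len(nrow(x))),
    location_id = sprintf("L%03d", seq_len(nrow(x))),
    patient_id = sprintf("P%02d", rep_len(1:6, nrow(x))),
    replicate = 1L, stringsAsFactors = FALSE)
  list(x = x, labels = labels, measurements = meas)
}

# All 2x2 confusion tables with a given total count.
all_tables_with_total <- function(total) {
  out <- list()
  for (tp in 0:total) for (fp in 0:(total - tp))
    for (tn in 0:(total - tp - fp)) {
      fn <- total - tp - fp - tn
      out[[length(out) + 1L]] <- c(TP = tp, FP = fp, TN = tn, FN = fn)
    }
  out
}
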