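#' Train the two-stage linear SVM cascade
#'
#' Stage one separates fat from everything else (wall and tumor merged into
#' one class); stage two is trained on wall and tumor spectra only and
#' separates the two. Both stages are linear support vector machines on the
#' normalized spectra, with no feature scaling beyond the 800 nm
#' normalization. The fitted hyperplanes are stored as explicit weight
#' vectors, oriented so that a positive `score_fat` means fat and a
#' positive `score_tumor` means tumor.
#'
#' @param x Numeric matrix of normalized spectra, one row per measurement.
#' @param labels Character or factor vector over `{"fat","wall","tumor"}`.
#' @param cost SVM regularization cost (default 1).
#' @param tumor_threshold Decision threshold on the signed tumor score
#'   (default 0); a spectrum routed past stage one is called tumor only if
#'   its score strictly exceeds this.
#' @return An object of class `drs_cascade` with elements `w_fat`, `b_fat`,
#'   `w_tumor`, `b_tumor`, `tumor_threshold`, `wavelength` (column names).
#' @export
train_cascade <- function(x, labels, cost = 1, tumor_threshold = 0) {
  labels <- as.character(labels)
  if (!all(labels %in% c("fat", "wall", "tumor"))) {
    stop("labels must be fat, wall or tumor", call. = FALSE)
  }
  if (nrow(x) != length(labels)) {
    stop("x and labels disagree in length", call. = FALSE)
  }
  if (!any(labels %in% c("wall", "tumor")) ||
      length(unique(labels)) < 2L ||
      (sum(labels == "wall") > 0) + (sum(labels == "tumor") > 0) < 2L) {
    stop("training requires fat/non-fat contrast and both wall and tumor",
         call. = FALSE)
  }
  h1 <- fit_linear_svm(x, labels == "fat", cost)
  sel <- labels %in% c("wall", "tumor")
  h2 <- fit_linear_svm(x[sel, , drop = FALSE], labels[sel] == "tumor", cost)
  structure(list(w_fat = h1$w, b_fat = h1$b,
                 w_tumor = h2$w, b_tumor = h2$b,
                 tumor_threshold = tumor_threshold,
                 cost = cost, wavelength = colnames(x)),
            class = "drs_cascade")
}

# Fit a binary linear SVM and return (w, b) oriented so that
# x %*% w + b > 0 on the positive class side.
fit_linear_svm <- function(x, positive, cost) {
  y <- factor(ifelse(positive, "pos", "neg"), levels = c("pos", "neg"))
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to fit a discriminant", call. = FALSE)
  }
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  s <- drop(x %*% w) + b
  # orient by the training-set class means of the signed score
  if (mean(s[positive]) < mean(s[!positive])) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

cascade_scores <- function(object, x) {
  if (ncol(x) != length(object$w_fat)) {
    stop("spectrum dimensionality does not match the model", call. = FALSE)
  }
  list(score_fat = drop(x %*% object$w_fat) + object$b_fat,
       score_tumor = drop(x %*% object$w_tumor) + object$b_tumor)
}

#' Predict tissue classes with a trained cascade
#'
#' Routing follows the study workflow: a spectrum on the fat side of stage
#' one is called fat and never reaches stage two; otherwise it is called
#' tumor if its tumor score strictly exceeds the model's threshold, and
#' healthy colorectal wall otherwise. Ties at either boundary fall to the
#' healthy side. `score_tumor` is reported as `NA` for fat-routed spectra
#' (stage two was not consulted); `keep_tumor_scores = TRUE` reports the
#' stage-two score for every spectrum, which threshold analyses need.
#'
#' @param object A `drs_cascade`.
#' @param x Matrix of normalized spectra (or a single spectrum vector).
#' @param keep_tumor_scores Report stage-two scores for fat-routed spectra
#'   too (default `FALSE`).
#' @param ... Unused.
#' @return A data frame with `score_fat`, `score_tumor`, `predicted_class`.
#' @export
predict.drs_cascade <- function(object, x, keep_tumor_scores = FALSE, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  sc <- cascade_scores(object, x)
  is_fat <- sc$score_fat > 0
  is_tumor <- !is_fat & sc$score_tumor > object$tumor_threshold
  cls <- ifelse(is_fat, "fat", ifelse(is_tumor, "tumor", "wall"))
  st <- sc$score_tumor
  if (!keep_tumor_scores) st[is_fat] <- NA_real_
  data.frame(score_fat = sc$score_fat, score_tumor = st,
             predicted_class = cls, stringsAsFactors = FALSE)
}

# Stratified assignment of locations to k folds; with grouping, whole
# patients are assigned to folds (round-robin over a shuffled patient list)
# so no patient spans two folds.
assign_folds <- function(locations, k, group_by_patient = FALSE) {
  n <- nrow(locations)
  fold <- integer(n)
  if (group_by_patient) {
    patients <- sample(unique(locations$patient_id))
    pf <- rep_len(seq_len(k), length(patients))
    fold <- pf[match(locations$patient_id, patients)]
  } else {
    for (cls in unique(locations$true_class)) {
      idx <- which(locations$true_class == cls)
      if (length(idx) < k) {
        stop(sprintf("class '%s' has %d locations, fewer than k = %d folds",
                     cls, length(idx), k), call. = FALSE)
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the cascade
#'
#' The fold unit is the measurement location, so the replicate spectra of
#' one site always stay in the same fold; folds are stratified by tissue
#' class (or, optionally, grouped by patient so no patient spans folds).
#' Per repeat, each measurement receives exactly one out-of-fold
#' prediction; with the default ten folds and ten repeats every spectrum is
#' predicted ten times by models that never saw its location.
#'
#' @param features Matrix of normalized spectra (rows = measurements).
#' @param measurements Data frame with `measurement_id`, `location_id`,
#'   `patient_id` matching the feature rows.
#' @param labels Class label per measurement (fat/wall/tumor).
#' @param k Number of folds (default 10).
#' @param repeats Number of repetitions (default 10).
#' @param seed Integer seed for the fold assignments.
#' @param group_by_patient Keep each patient inside one fold (default
#'   `FALSE`).
#' @param cost,tumor_threshold Passed to [train_cascade()].
#' @return Data frame of prediction records: measurement id, location id,
#'   repeat and fold indices, both scores, predicted and true class.
#' @export
cross_validate <- function(features, measurements, labels, k = 10,
                           repeats = 10, seed = 1L,
                           group_by_patient = FALSE, cost = 1,
                           tumor_threshold = 0) {
  stopifnot(nrow(features) == nrow(measurements),
            length(labels) == nrow(features))
  labels <- as.character(labels)
  first <- !duplicated(measurements$location_id)
  loc <- data.frame(location_id = measurements$location_id[first],
                    patient_id = measurements$patient_id[first],
                    true_class = labels[first],
                    stringsAsFactors = FALSE)
  set.seed(seed)
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold_of_loc <- assign_folds(loc, k, group_by_patient)
    fold <- fold_of_loc[match(measurements$location_id, loc$location_id)]
    preds <- vector("list", k)
    for (f in seq_len(k)) {
      test <- fold == f
      if (!any(test)) next
      model <- train_cascade(features[!test, , drop = FALSE], labels[!test],
                             cost = cost, tumor_threshold = tumor_threshold)
      p <- predict(model, features[test, , drop = FALSE],
                   keep_tumor_scores = TRUE)
      preds[[f]] <- cbind(
        data.frame(measurement_id = measurements$measurement_id[test],
                   location_id = measurements$location_id[test],
                   patient_id = measurements$patient_id[test],
                   repeat_index = r, fold = f,
                   true_class = labels[test], stringsAsFactors = FALSE),
        p)
    }
    out[[r]] <- do.call(rbind, preds)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate replicate predictions to one call per location
#'
#' The location-level class is the majority vote of its replicate
#' predictions (ties broken by re-running the cascade routing on the mean
#' replicate scores); the location-level scores are the means of the
#' replicate scores. Used for the per-location analyses (threshold
#' calibration and comparison with surgeon judgement).
#'
#' @param predictions Prediction records from [cross_validate()].
#' @param tumor_threshold Threshold used in the tie-break routing.
#' @return One row per location x repeat with mean scores, the voted class
#'   and the true class.
#' @export
aggregate_locations <- function(predictions, tumor_threshold = 0) {
  key <- interaction(predictions$location_id, predictions$repeat_index,
                     drop = TRUE)
  rows <- lapply(split(predictions, key), function(d) {
    tab <- table(d$predicted_class)
    top <- names(tab)[tab == max(tab)]
    mf <- mean(d$score_fat)
    mt <- mean(d$score_tumor)
    cls <- if (length(top) == 1L) top else {
      if (mf > 0) "fat" else if (mt > tumor_threshold) "tumor" else "wall"
    }
    data.frame(location_id = d$location_id[1],
               patient_id = d$patient_id[1],
               repeat_index = d$repeat_index[1],
               score_fat = mf, score_tumor = mt,
               predicted_class = cls, true_class = d$true_class[1],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Serialize a cascade model to JSON
#'
#' Writes the two hyperplanes (weights and bias), the tumor threshold and
#' the wavelength grid to a JSON document; [read_cascade()] restores it.
#'
#' @param model A `drs_cascade`.
#' @param path Output file path.
#' @export
write_cascade <- function(model, path) {
  stopifnot(inherits(model, "drs_cascade"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cascade
#' @export
read_cascade <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$w_fat <- as.numeric(m$w_fat)
  m$w_tumor <- as.numeric(m$w_tumor)
  structure(m, class = "drs_cascade")
}
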