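#' Depth-based tumor labeling rule
#'
#' The probe senses roughly as deep as its 1.29 mm fiber separation, so a
#' location counts as tumor when tumor tissue starts within `max_depth_mm`
#' of the measurement surface (default 1.5 mm). A location whose tumor lies
#' within that depth but extends laterally less than `min_extent_mm`
#' (default 0.5 mm) cannot be reliably correlated with histopathology and
#' is excluded as inconclusive.
#'
#' @param max_depth_mm Maximum depth for a tumor label, mm (> 0 allowed to
#'   be 0 for surface-only labeling).
#' @param min_extent_mm Minimum lateral tumor extent for a conclusive
#'   label, mm (> 0).
#' @return An object of class `depth_rule`.
#' @export
depth_rule <- function(max_depth_mm = 1.5, min_extent_mm = 0.5) {
  if (max_depth_mm < 0 || min_extent_mm <= 0) {
    stop("max_depth_mm must be >= 0 and min_extent_mm > 0", call. = FALSE)
  }
  structure(list(max_depth_mm = max_depth_mm, min_extent_mm = min_extent_mm),
            class = "depth_rule")
}

#' Label locations by the depth rule
#'
#' Tumor-containing locations become `"tumor"` when the tumor starts within
#' the rule's depth and is laterally conclusive, `"excluded"` when within
#' depth but inconclusive (extent below the minimum), and `"non_tumor"`
#' when the tumor starts deeper than the rule allows. Locations without
#' tumor are `"non_tumor"`.
#'
#' @param locations Locations data frame of a `drs_dataset` (columns
#'   `true_class`, `tumor_depth_mm`, `tumor_extent_mm`).
#' @param rule A [depth_rule].
#' @return Character vector over `{"tumor", "non_tumor", "excluded"}`.
#' @export
depth_label <- function(locations, rule = depth_rule()) {
  stopifnot(inherits(rule, "depth_rule"))
  has_tumor <- locations$true_class == "tumor"
  if (any(has_tumor & !is.finite(locations$tumor_depth_mm))) {
    stop("tumor location without a recorded depth", call. = FALSE)
  }
  out <- rep("non_tumor", nrow(locations))
  within <- has_tumor & locations$tumor_depth_mm <= rule$max_depth_mm
  out[within] <- ifelse(
    locations$tumor_extent_mm[within] >= rule$min_extent_mm,
    "tumor", "excluded")
  out
}

# Classification labels under a depth rule: tumor-containing locations
# relabeled by depth_label (deep tumors present a healthy wall surface and
# are labeled wall); excluded locations dropped via the keep flag.
rule_labels <- function(locations, rule = depth_rule()) {
  dl <- depth_label(locations, rule)
  labels <- ifelse(locations$true_class == "tumor",
                   ifelse(dl == "tumor", "tumor", "wall"),
                   locations$true_class)
  list(labels = labels, keep = dl != "excluded", depth_label = dl)
}

#' Sweep the maximum tumor depth and re-run the classification
#'
#' For each maximum depth, tumor-containing locations are relabeled (tumor
#' when the tumor starts within that depth, healthy wall when deeper;
#' inconclusive locations dropped), the cascade is re-trained and re-tested
#' by cross-validation from scratch, and the tumor-vs-all accuracy and MCC
#' are recorded. Reproduces the depth-dependence analysis: performance
#' peaks when the depth label matches the probe's 1-1.5 mm sensing depth
#' and declines as deeper, optically invisible tumors are forced into the
#' tumor class.
#'
#' @param dataset A `drs_dataset`.
#' @param depths Maximum-depth grid in mm (default
#'   `c(0, 1, 1.5, 2, 3, 4, Inf)`; `Inf` = "more than 4 mm", no depth
#'   limit).
#' @param min_extent_mm Conclusiveness threshold (default 0.5).
#' @param k,repeats,seed,cost,group_by_patient Cross-validation settings,
#'   as in [cross_validate()].
#' @param features Optional preprocessed features (from
#'   [preprocess_dataset()]); computed if missing.
#' @return Data frame per depth: number of tumor-labeled locations, mean
#'   and SD of tumor accuracy and MCC across repeats, and an `empty` flag
#'   for depth bins containing no tumor-labeled locations (such bins carry
#'   `NA` metrics rather than being silently dropped).
#' @export
depth_sweep <- function(dataset, depths = c(0, 1, 1.5, 2, 3, 4, Inf),
                        min_extent_mm = 0.5, k = 10, repeats = 10,
                        seed = 1L, cost = 1, group_by_patient = FALSE,
                        features = NULL) {
  stopifnot(inherits(dataset, "drs_dataset"))
  if (is.null(features)) features <- preprocess_dataset(dataset)
  rows <- vector("list", length(depths))
  for (i in seq_along(depths)) {
    rule <- depth_rule(max_depth_mm = depths[i],
                       min_extent_mm = min_extent_mm)
    rl <- rule_labels(dataset$locations, rule)
    keep_loc <- dataset$locations$location_id[rl$keep]
    n_tumor <- sum(rl$labels[rl$keep] == "tumor")
    if (n_tumor == 0L) {
      rows[[i]] <- data.frame(max_depth_mm = depths[i], n_tumor_locations = 0L,
                              k_used = NA_integer_,
                              accuracy_mean = NA_real_, accuracy_sd = NA_real_,
                              mcc_mean = NA_real_, mcc_sd = NA_real_,
                              empty = TRUE)
      next
    }
    sel <- dataset$measurements$location_id %in% keep_loc
    meas <- dataset$measurements[sel, , drop = FALSE]
    lab <- rl$labels[rl$keep][match(meas$location_id, keep_loc)]
    # sparse depth bins: shrink the fold count to the smallest class so the
    # bin still yields a value (k_used records the reduction)
    k_eff <- min(k, min(table(rl$labels[rl$keep])))
    preds <- cross_validate(features$features[sel, , drop = FALSE], meas,
                            lab, k = k_eff, repeats = repeats, seed = seed,
                            cost = cost, group_by_patient = group_by_patient)
    per_rep <- vapply(split(preds, preds$repeat_index), function(d) {
      cc <- confusion(d$predicted_class, d$true_class, "tumor")
      c(basic_rates(cc)$accuracy, mcc(cc))
    }, numeric(2))
    rows[[i]] <- data.frame(
      max_depth_mm = depths[i], n_tumor_locations = n_tumor, k_used = k_eff,
      accuracy_mean = mean(per_rep[1, ]), accuracy_sd = stats::sd(per_rep[1, ]),
      mcc_mean = mean(per_rep[2, ]), mcc_sd = stats::sd(per_rep[2, ]),
      empty = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Calibrate the zero-false-negative tumor threshold
#'
#' To rule out positive resection margins, the tumor decision threshold is
#' lowered until every true tumor location in the calibration subset (the
#' locations the surgeon was certain about) is called tumor: the threshold
#' is placed just below the minimum tumor score - at the midpoint between
#' it and the next distinct score below, or a fixed epsilon below it when
#' it is the global minimum. This yields zero false negatives on the
#' calibration subset by construction, with the fewest false positives
#' compatible with that constraint. A healthy location scoring exactly at
#' the minimum tumor score is counted a false positive (the tie is called
#' tumor).
#'
#' @param scores Location-level tumor scores of the calibration subset.
#' @param truths Logical (or 0/1): is the location truly tumor.
#' @return An object of class `threshold_calibration`: `threshold`,
#'   `n_calibration`, `fn` (always 0), `fp`.
#' @export
zero_fn_threshold <- function(scores, truths) {
  truths <- as.logical(truths)
  if (length(scores) != length(truths)) {
    stop("scores and truths must have the same length", call. = FALSE)
  }
  if (!any(truths)) {
    stop("calibration subset contains no tumor locations", call. = FALSE)
  }
  min_t <- min(scores[truths])
  below <- scores[scores < min_t]
  threshold <- if (length(below)) (min_t + max(below)) / 2 else min_t - 1e-6
  called <- scores > threshold
  structure(list(threshold = threshold, n_calibration = length(scores),
                 fn = sum(truths & !called), fp = sum(!truths & called)),
            class = "threshold_calibration")
}

#' Compare calibrated classifier and surgeon on the uncertain locations
#'
#' Locations are collapsed to healthy (fat or wall) versus tumor. On the
#' subset the surgeon judged with certainty, the tumor threshold is
#' calibrated so the classifier makes no false negatives
#' ([zero_fn_threshold()]); that threshold is then applied to the uncertain
#' locations and the classifier's 2x2 table against histopathology is set
#' beside the surgeon's. The thresholded call uses the location-level
#' stage-two score (mean of the replicates' out-of-fold tumor scores,
#' averaged over CV repeats), so the calibration never sees resubstitution
#' scores.
#'
#' @param dataset A `drs_dataset`.
#' @param predictions Prediction records from [cross_validate()] run with
#'   stage-two scores for all spectra; if `NULL`, computed here.
#' @param rule The [depth_rule] defining histopathology truth; inconclusive
#'   locations are excluded.
#' @param k,repeats,seed,cost CV settings used when `predictions` is `NULL`.
#' @return List with the calibration, the two `drs_confusion` tables
#'   (`classifier`, `surgeon`), their false-positive rates among
#'   healthy-truth locations and classifier sensitivity/specificity, and
#'   the uncertain-subset size.
#' @export
compare_with_surgeon <- function(dataset, predictions = NULL,
                                 rule = depth_rule(), k = 10, repeats = 10,
                                 seed = 1L, cost = 1) {
  stopifnot(inherits(dataset, "drs_dataset"))
  rl <- rule_labels(dataset$locations, rule)
  keep <- rl$keep
  if (is.null(predictions)) {
    features <- preprocess_dataset(dataset)
    sel <- dataset$measurements$location_id %in%
      dataset$locations$location_id[keep]
    lab <- rl$labels[keep][match(dataset$measurements$location_id[sel],
                                 dataset$locations$location_id[keep])]
    predictions <- cross_validate(
      features$features[sel, , drop = FALSE],
      dataset$measurements[sel, , drop = FALSE], lab,
      k = k, repeats = repeats, seed = seed, cost = cost)
  }
  # one tumor score per location: mean over replicates and repeats
  sc <- tapply(predictions$score_tumor, predictions$location_id, mean)
  loc <- dataset$locations[keep, , drop = FALSE]
  loc <- loc[loc$location_id %in% names(sc), , drop = FALSE]
  loc$score <- as.numeric(sc[loc$location_id])
  loc$truth_tumor <- rl$labels[keep][match(loc$location_id,
                                           dataset$locations$location_id[keep])] == "tumor"
  cal_set <- loc[loc$surgeon_certain, , drop = FALSE]
  unc_set <- loc[!loc$surgeon_certain, , drop = FALSE]
  if (nrow(unc_set) == 0L) {
    stop("no uncertain locations to evaluate", call. = FALSE)
  }
  calibration <- zero_fn_threshold(cal_set$score, cal_set$truth_tumor)
  cls_call <- ifelse(unc_set$score > calibration$threshold,
                     "tumor", "healthy")
  truth <- ifelse(unc_set$truth_tumor, "tumor", "healthy")
  classifier <- confusion(cls_call, truth, "tumor")
  surgeon <- confusion(unc_set$surgeon_class, truth, "tumor")
  fp_rate <- function(cc) if (cc$FP + cc$TN > 0)
    cc$FP / (cc$FP + cc$TN) else NA_real_
  rates <- basic_rates(classifier)
  list(calibration = calibration, classifier = classifier, surgeon = surgeon,
       classifier_fp_rate = fp_rate(classifier),
       surgeon_fp_rate = fp_rate(surgeon),
       classifier_sensitivity = rates$sensitivity,
       classifier_specificity = rates$specificity,
       n_uncertain = nrow(unc_set), n_certain = nrow(cal_set))
}
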