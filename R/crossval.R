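#' Patient-level k-fold partition
#'
#' Shuffled balanced partition of patients into `k` disjoint validation
#' folds whose sizes differ by at most one (30 patients in 5 folds give
#' six validation patients per fold, with the remaining 24 forming each
#' training set). Assignment is by patient, never by slice, so no
#' patient contributes slices to both sides of a split.
#'
#' @param patient_ids character vector of unique patient identifiers.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return An object of class `fold_plan`: list with `k`, `assignments`
#'   (named integer vector patient -> fold) and `seed`.
#' @export
make_folds <- function(patient_ids, k = 5L, seed = 1L) {
  stop_if_not(k >= 2, "k must be at least 2")
  stop_if_not(!anyDuplicated(patient_ids), "patient_ids must be unique")
  n <- length(patient_ids)
  stop_if_not(n >= k, "need at least k patients")
  ord <- with_seed(as.integer(seed), sample.int(n))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  assignments <- stats::setNames(rep(seq_len(k), sizes), patient_ids[ord])
  assignments <- assignments[patient_ids]   # original order
  structure(list(k = as.integer(k), assignments = assignments,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds over %d patients (seed %d): sizes %s\n",
              x$k, length(x$assignments), x$seed,
              paste(tabulate(x$assignments, x$k), collapse = ", ")))
  invisible(x)
}

#' Evaluate a predicted structure against its ground truth
#'
#' Computes the full per-structure metric block: volumetric Dice and
#' Jaccard (on masks rasterized onto the CT grid), contour-based HD95,
#' and effective length and radius of both the prediction and the
#' truth.
#'
#' @param pred,truth [structure_set]s containing `structure_pred` /
#'   `structure_truth`.
#' @param grid the CT [image_volume] defining the evaluation grid.
#' @param structure_pred,structure_truth structure names.
#' @return A one-row data.frame with columns `dsc`, `jsc`, `hd95_mm`,
#'   `length_mm`, `radius_mm`, `truth_length_mm`, `truth_radius_mm`.
#' @export
evaluate_structure_pair <- function(pred, truth, grid,
                                    structure_pred, structure_truth) {
  mp <- rasterize(pred, grid, structure_pred)
  mt <- rasterize(truth, grid, structure_truth)
  has_pred <- length(pred$structures[[structure_pred]]$contours) > 0
  data.frame(
    dsc = dice(mp, mt),
    jsc = jaccard(mp, mt),
    hd95_mm = if (has_pred) hd95(pred, truth, structure_pred, structure_truth)
              else NA_real_,
    length_mm = if (has_pred) effective_length(pred, structure_pred)
                else NA_real_,
    radius_mm = if (has_pred) effective_radius(pred, structure_pred)
                else NA_real_,
    truth_length_mm = effective_length(truth, structure_truth),
    truth_radius_mm = effective_radius(truth, structure_truth))
}

# Validation-fold (probability, reference) pairs in the model's native
# (right-side) frame: native CT with the right mask, mirrored CT with
# the mirrored left mask.
validation_pairs <- function(model, patients) {
  probs <- list(); refs <- list()
  for (pat in patients) {
    nms <- structure_names(pat$truth)
    lats <- vapply(pat$truth$structures, `[[`, character(1), "laterality")
    r_nm <- nms[match("right", lats)]
    l_nm <- nms[match("left", lats)]
    probs[[length(probs) + 1L]] <- predict_slices(model, pat$ct)
    refs[[length(refs) + 1L]] <- rasterize(pat$truth, pat$ct, r_nm)
    probs[[length(probs) + 1L]] <-
      predict_slices(model, mirror_lateral(pat$ct))
    refs[[length(refs) + 1L]] <-
      mask_volume(mirror_lateral(rasterize(pat$truth, pat$ct, l_nm))$voxels,
                  pat$ct)
  }
  list(probs = probs, refs = refs)
}

#' Run patient-level cross-validation of the pooled gland model
#'
#' For every fold: builds the laterality-pooled training set from the
#' other folds' patients, trains one combined model, tunes the
#' binarization threshold on the fold's validation patients, predicts
#' both glands for each validation patient and scores them against the
#' ground truth. The threshold for a fold is selected only on that
#' fold's validation patients after training only on the remaining
#' patients (asserted at run time), mirroring the absence of a separate
#' test set. Fold metrics are aggregated as fold means, then mean and
#' sd across folds.
#'
#' @param cohort list of patients (`ct`, `truth`, `patient_id`), e.g.
#'   from [generate_cohort()].
#' @param config a [model_config]; each fold's model derives its seed
#'   from `config$seed` and the fold index.
#' @param fold_plan a [fold_plan] covering every cohort patient.
#' @param slice_range passed to [build_pooled_dataset()] (default
#'   [band_slices()] with a 4-slice margin).
#' @param candidates threshold grid for [select_threshold()].
#' @param keep_largest passed to [predict_structure()].
#' @param verbose print per-fold progress.
#' @return A list with `folds` (per-fold blocks: patients, threshold,
#'   per-structure metrics, trained model) and `aggregate`
#'   (see [aggregate_folds()]).
#' @export
run_cross_validation <- function(cohort, config, fold_plan,
                                 slice_range = band_slices(4L),
                                 candidates = seq(0.05, 0.95, by = 0.05),
                                 keep_largest = FALSE, verbose = FALSE) {
  ids <- vapply(cohort, function(p) p$patient_id, character(1))
  stop_if_not(setequal(ids, names(fold_plan$assignments)),
              "fold plan must cover exactly the cohort patients")
  fold_of <- fold_plan$assignments[ids]
  folds <- list()
  metric_rows <- list()
  metric_folds <- integer(0)
  for (f in seq_len(fold_plan$k)) {
    train_idx <- which(fold_of != f)
    val_idx <- which(fold_of == f)
    stop_if_not(length(train_idx) > 0 && length(val_idx) > 0,
                "fold %d has an empty side", f)
    if (verbose) {
      message(sprintf("fold %d/%d: %d training, %d validation patients",
                      f, fold_plan$k, length(train_idx), length(val_idx)))
    }
    samples <- build_pooled_dataset(cohort[train_idx],
                                    window = config$window_hu,
                                    slice_range = slice_range)
    fold_config <- config
    fold_config$seed <- config$seed + 1000L * f
    model <- build_multiresunet(fold_config)
    model$trained_on <- ids[train_idx]
    model <- tryCatch(
      train_multiresunet(model, samples, fold_config, verbose = verbose),
      error = function(e) stop(sprintf("fold %d: %s", f, conditionMessage(e)),
                               call. = FALSE))
    # leak guard: threshold tuning must only see held-out patients
    stop_if_not(!any(ids[val_idx] %in% model$trained_on),
                "fold %d: validation patient in training set", f)
    vp <- validation_pairs(model, cohort[val_idx])
    model <- set_threshold(model,
                           select_threshold(vp$probs, vp$refs, candidates))
    rows <- list()
    for (i in val_idx) {
      pat <- cohort[[i]]
      nms <- structure_names(pat$truth)
      lats <- vapply(pat$truth$structures, `[[`, character(1), "laterality")
      for (side in c("right", "left")) {
        pred <- predict_structure(model, pat$ct, side = side,
                                  keep_largest = keep_largest)
        truth_nm <- nms[match(side, lats)]
        row <- evaluate_structure_pair(pred$structure, pat$truth, pat$ct,
                                       structure_names(pred$structure),
                                       truth_nm)
        row <- cbind(data.frame(patient_id = pat$patient_id, side = side,
                                fold = f), row)
        rows[[length(rows) + 1L]] <- row
        metric_rows[[length(metric_rows) + 1L]] <- row
        metric_folds <- c(metric_folds, f)
      }
    }
    folds[[f]] <- list(fold = f, patients = ids[val_idx],
                       threshold = model$threshold,
                       metrics = do.call(rbind, rows),
                       model = model)
  }
  per_structure <- do.call(rbind, metric_rows)
  aggregate <- aggregate_folds(
    per_structure, metric_folds,
    metrics = c("dsc", "jsc", "hd95_mm", "length_mm", "radius_mm"))
  list(folds = folds, aggregate = aggregate, per_structure = per_structure,
       fold_plan = fold_plan)
}
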