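#' Confusion counts from predicted and true binary labels
#'
#' @param truth,estimate Integer vectors of 0/1 labels (1 = positive).
#' @return A `confusion_counts` list `(tp, tn, fp, fn)`.
#' @export
confusion_counts <- function(truth, estimate) {
  check_that(length(truth) == length(estimate), "estimate", "length mismatch with truth")
  structure(list(tp = sum(truth == 1 & estimate == 1),
                 tn = sum(truth == 0 & estimate == 0),
                 fp = sum(truth == 0 & estimate == 1),
                 fn = sum(truth == 1 & estimate == 0)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)` (true-positive
#' rate), specificity `TN/(TN+FP)` (true-negative rate). Undefined
#' denominators raise an error rather than returning NaN.
#'
#' @param counts A [confusion_counts()] or a list with `tp, tn, fp, fn`.
#' @return A tibble with columns `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' compute_metrics(list(tp = 45, tn = 45, fp = 5, fn = 5))
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    total <- tp + tn + fp + fn
    if (total == 0) abort("empty evaluation: all confusion counts are zero",
                          class = "bcdnet_state_error")
    if (tp + fn == 0) abort("sensitivity undefined: no positive samples",
                            class = "bcdnet_state_error")
    if (tn + fp == 0) abort("specificity undefined: no negative samples",
                            class = "bcdnet_state_error")
    tibble::tibble(accuracy = (tp + tn) / total,
                   sensitivity = tp / (tp + fn),
                   specificity = tn / (tn + fp))
  })
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt into K folds from a fold counter that carries across classes, so
# folds stay balanced and every fold is used even when K exceeds a class
# size (K = n gives leave-one-out). Internal.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    start <- 0L
    for (lb in unique(labels)) {
      idx <- sample(which(labels == lb))
      fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
    fold
  })
}

#' Stratified K-fold evaluation of the feature-based classifier
#'
#' Splits the samples into K stratified folds (seeded), trains on K-1 folds
#' and evaluates on the held-out fold. Augmentation, when requested, is
#' applied to the training folds only, after splitting, so no augmented copy
#' of a test image ever reaches training.
#'
#' @param samples Sample tibble (columns `id`, `label`, `image`, `mask`).
#' @param k Number of folds (>= 2; `k = nrow(samples)` gives leave-one-out).
#' @param classifier_cfg A [classifier_config()].
#' @param augment_cfg Optional [augment_spec()] applied to training folds.
#' @param seed Integer seed for the fold assignment.
#' @param frequencies,orientations,levels Feature-bank layout.
#' @return A `bcdnet_kfold` list: `per_fold` tibble of metrics, `summary`
#'   tibble of mean and sd.
#' @export
kfold_evaluate <- function(samples, k = 5, classifier_cfg = classifier_config(),
                           augment_cfg = NULL, seed = 1L,
                           frequencies = c(0.1, 0.2, 0.3, 0.4),
                           orientations = c(0, 45, 90, 135), levels = 256) {
  check_that(is_count(k) && k >= 2 && k <= nrow(samples), "k",
             "must be an integer in [2, n]")
  fold <- stratified_folds(samples$label, k, seed)
  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    train <- samples[fold != f, ]
    test <- samples[fold == f, ]
    if (!is.null(augment_cfg)) train <- augment_dataset(train, augment_cfg)
    ftr <- extract_features(train, frequencies, orientations, levels,
                            keep_stack = classifier_cfg$use_conv)
    fte <- extract_features(test, frequencies, orientations, levels,
                            keep_stack = classifier_cfg$use_conv)
    model <- train_classifier(ftr, classifier_cfg)
    pred <- predict(model, fte)
    cc <- confusion_counts(fte$label, pred$.pred_label)
    mets <- if (sum(fte$label == 1) > 0 && sum(fte$label == 0) > 0) {
      compute_metrics(cc)
    } else {
      # leave-one-out folds hold a single class; report accuracy only
      tibble::tibble(accuracy = (cc$tp + cc$tn) / length(fte$label),
                     sensitivity = NA_real_, specificity = NA_real_)
    }
    dplyr::bind_cols(tibble::tibble(fold = f, n_test = nrow(test)), mets)
  })
  summary <- tidyr::pivot_longer(per_fold, c("accuracy", "sensitivity", "specificity"),
                                 names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$metric),
                              mean = mean(.data$value, na.rm = TRUE),
                              sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  structure(list(per_fold = per_fold, summary = summary, k = k, seed = seed),
            class = "bcdnet_kfold")
}

#' @export
print.bcdnet_kfold <- function(x, ...) {
  cat(sprintf("<bcdnet_kfold> %d folds\n", x$k))
  print(x$summary)
  invisible(x)
}

#' @export
#' @rdname kfold_evaluate
#' @param x A `bcdnet_kfold`.
#' @param ... Unused.
tidy.bcdnet_kfold <- function(x, ...) x$per_fold

#' @export
#' @rdname kfold_evaluate
glance.bcdnet_kfold <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric", values_from = c("mean", "sd"))
}
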