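#' Run the full detection pipeline
#'
#' Executes the stages in order — denoise (adaptive Kalman filter), segment
#' (pyramid-pooling network trained by jellyfish search on a subset of
#' training images), augment (training split only), featurize (Gabor + LBP +
#' LVP + shape + histogram statistics), classify (error-similarity-weighted
#' CNN/dense classifier), metrics — on a phantom dataset generated from the
#' configuration, or on samples loaded from a manifest. Every stage draws its
#' seed from the single `config$seed`, so identical configurations give
#' identical reports.
#'
#' @param config A [default_config()] / [merge_config()] result.
#' @param manifest Optional manifest CSV path; when `NULL`, phantoms are
#'   generated from `config$phantom`.
#' @param n_per_class Phantom samples per class when generating.
#' @param holdout_fraction Fraction of each class held out for testing.
#' @param out_dir Optional directory for stage artifacts (segmentation maps,
#'   features CSV, report JSON, run log).
#' @return A `bcdnet_report` list: `metrics` tibble, `confusion` counts,
#'   `segmenter` fit, `classifier` fit, `n_train`, `n_test`, `config_hash`.
#' @export
run_pipeline <- function(config = default_config(), manifest = NULL,
                         n_per_class = 150, holdout_fraction = 1 / 3,
                         out_dir = NULL) {
  check_that(inherits(config, "pipeline_config"), "config", "must be a pipeline_config")
  stage <- "acquire"
  report <- tryCatch({
    samples <- if (is.null(manifest)) {
      generate_phantoms(config_phantom_spec(config), n_per_class)
    } else {
      read_samples(manifest)
    }

    # train/test split, stratified by class
    fold <- stratified_folds(samples$label, k = max(2L, round(1 / holdout_fraction)),
                             seed = stage_seed(config$seed, "folds"))
    test_idx <- fold == 1L
    train <- samples[!test_idx, ]
    test <- samples[test_idx, ]

    stage <- "preprocess"
    akf_cfg <- do.call(akf_config, config$akf)
    train <- dplyr::mutate(train, image = purrr::map(.data$image, akf_filter, config = akf_cfg))
    test <- dplyr::mutate(test, image = purrr::map(.data$image, akf_filter, config = akf_cfg))

    stage <- "segment"
    arch <- seg_architecture(preset = config$segmenter$preset)
    jso_cfg <- do.call(jso_config, c(config$jso, list(seed = stage_seed(config$seed, "segment"))))
    # train the lesion segmenter on lesion-bearing images (nonempty masks)
    lesioned <- which(purrr::map_lgl(train$mask, ~!is.null(.x) && sum(.x) > 0))
    if (length(lesioned) == 0) {
      abort("no training sample carries a nonempty mask; cannot train the segmenter",
            class = "bcdnet_stage_error")
    }
    sub_idx <- with_seed(stage_seed(config$seed, "segment"),
                         sample(lesioned, min(config$segmenter$train_subset,
                                              length(lesioned))))
    seg <- train_segmenter(train[sub_idx, ], arch, jso_cfg, bound = config$segmenter$bound)
    predict_mask <- function(img, orig_dim) {
      p <- seg_forward(img, seg$theta, seg$arch)
      resize_mask(binarize(p, config$segmenter$threshold), orig_dim)
    }
    train <- dplyr::mutate(train, mask = purrr::map(.data$image, ~predict_mask(.x, dim(.x))))
    test <- dplyr::mutate(test, mask = purrr::map(.data$image, ~predict_mask(.x, dim(.x))))

    stage <- "augment"
    aug_cfg <- do.call(augment_spec, c(config$augment,
                                       list(seed = stage_seed(config$seed, "augment"))))
    train_aug <- augment_dataset(train, aug_cfg)

    stage <- "featurize"
    cls_cfg <- do.call(classifier_config,
                       c(config$classifier,
                         list(n_classes = 2L, seed = stage_seed(config$seed, "classify"))))
    fcfg <- config$features
    ftr <- extract_features(train_aug, fcfg$frequencies, fcfg$orientations, fcfg$levels,
                            keep_stack = cls_cfg$use_conv)
    fte <- extract_features(test, fcfg$frequencies, fcfg$orientations, fcfg$levels,
                            keep_stack = cls_cfg$use_conv)

    stage <- "classify"
    model <- train_classifier(ftr, cls_cfg)
    pred <- predict(model, fte)

    stage <- "metrics"
    cc <- confusion_counts(fte$label, pred$.pred_label)
    mets <- compute_metrics(cc)

    structure(list(metrics = mets, confusion = cc, segmenter = seg, classifier = model,
                   predictions = dplyr::bind_cols(tibble::tibble(label = fte$label), pred),
                   n_train = nrow(train), n_test = nrow(test),
                   config_hash = config_hash(config), seed = config$seed),
              class = "bcdnet_report")
  }, error = function(e) {
    if (inherits(e, "bcdnet_stage_error")) stop(e)
    abort(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
          class = "bcdnet_stage_error", parent = e)
  })

  if (!is.null(out_dir)) write_report(report, out_dir, config)
  report
}

write_report <- function(report, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(metrics = as.list(report$metrics),
         confusion = unclass(report$confusion),
         n_train = report$n_train, n_test = report$n_test,
         config_hash = report$config_hash, seed = report$seed),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  log_lines <- c(sprintf("config_hash: %s", report$config_hash),
                 sprintf("seed: %d", report$seed),
                 sprintf("stage seeds: %s",
                         paste(sprintf("%s=%d",
                                       c("phantom", "akf", "segment", "augment",
                                         "features", "classify", "folds"),
                                       vapply(c("phantom", "akf", "segment", "augment",
                                                "features", "classify", "folds"),
                                              function(s) stage_seed(report$seed, s),
                                              integer(1))),
                               collapse = ", ")))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.bcdnet_report <- function(x, ...) {
  cat(sprintf("<bcdnet_report> %d train / %d test samples\n", x$n_train, x$n_test))
  print(x$metrics)
  invisible(x)
}

#' @export
#' @rdname run_pipeline
#' @param x A `bcdnet_report`.
#' @param ... Unused.
glance.bcdnet_report <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble::tibble(n_train = x$n_train, n_test = x$n_test, seed = x$seed))
}

#' @export
#' @rdname run_pipeline
tidy.bcdnet_report <- function(x, ...) {
  tibble::tibble(metric = names(x$metrics), value = as.numeric(x$metrics[1, ]))
}
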