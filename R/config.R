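#' Default pipeline configuration
#'
#' One sub-record per stage, mirroring that stage's tunables. A single global
#' `seed` fans out to fixed per-stage child seeds so every stage is
#' independently reproducible. Unknown keys are rejected when merging.
#'
#' @param seed Global integer seed.
#' @return A nested `pipeline_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    phantom = list(image_size = 64, lesion_axis_range = c(0.08, 0.20),
                   background_smoothness = 6, noise_sigma = 10,
                   noise_model = "gaussian", class_contrast = 40,
                   texture_frequency = c(0.15, 0.35), benign_lesion = FALSE),
    akf = list(window = 15, process_variance = 200, min_meas_variance = 1e-6,
               passes = "bidirectional"),
    jso = list(population = 20, iterations = 300, eta = 3, chi = 0.1, x0 = 0.5),
    segmenter = list(preset = "tiny", bound = 2, train_subset = 8, threshold = 0.5),
    augment = list(rotation_angles = c(90, 180, 270), erase_fraction_range = c(0.1, 0.3),
                   erase_fill = "zero", flips = c("vertical", "horizontal", "both"),
                   copies_per_image = 1),
    features = list(frequencies = c(0.1, 0.2, 0.3, 0.4),
                    orientations = c(0, 45, 90, 135), levels = 256),
    classifier = list(use_dense = TRUE, use_conv = FALSE, hidden = 16,
                      conv_channels = c(4, 8), learning_rate = 0.2,
                      epochs = 60, batch_size = 8, phi0 = 0, phi_max = 10),
    evaluation = list(k = 5)
  ), class = "pipeline_config")
}

#' Merge user overrides into the default configuration
#'
#' @param overrides Nested list (e.g. parsed from YAML); keys must exist in
#'   [default_config()], unknown keys raise an error naming the key.
#' @param base A `pipeline_config` to merge into.
#' @return The merged `pipeline_config`.
#' @export
merge_config <- function(overrides, base = default_config()) {
  if (is.null(overrides)) return(base)
  for (key in names(overrides)) {
    if (!key %in% names(base)) {
      abort(paste("unknown configuration key:", key), class = "bcdnet_validation_error")
    }
    if (is.list(base[[key]]) && is.list(overrides[[key]])) {
      for (sub in names(overrides[[key]])) {
        if (!sub %in% names(base[[key]])) {
          abort(paste0("unknown configuration key: ", key, ".", sub),
                class = "bcdnet_validation_error")
        }
        base[[key]][[sub]] <- overrides[[key]][[sub]]
      }
    } else {
      base[[key]] <- overrides[[key]]
    }
  }
  class(base) <- "pipeline_config"
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of overrides over [default_config()].
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste("config file not found:", path), class = "bcdnet_io_error")
  merge_config(yaml::read_yaml(path))
}

config_phantom_spec <- function(config) {
  do.call(phantom_spec, c(config$phantom, list(seed = stage_seed(config$seed, "phantom"))))
}

config_hash <- function(config) {
  # stable short fingerprint of the effective configuration for run logs
  s <- yaml::as.yaml(unclass(config))
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 100000000
}
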