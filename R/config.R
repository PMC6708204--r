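#' Default pipeline configuration
#'
#' All tunables of the segmentation pipeline with their defaults:
#' `similarity_threshold` 0.81 (grid-cell asymmetry), `background_threshold`
#' 5 (mean superpixel intensity), `annotation_threshold` 0.5 (superpixel
#' overlap fraction), the K search grid 10..450 step 10, `merge_ratio` 0.9,
#' `plateau_epsilon` 0.01, 10 SLIC iterations, quantization levels
#' 8/16/32/64, co-occurrence directions 0/45/90/135, 4 Otsu channels, 5
#' forest trees, 5 CV folds, train fraction 0.8, and the seed.
#'
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function() {
  validate_config(list(
    similarity_threshold = 0.81,
    background_threshold = 5,
    annotation_threshold = 0.5,
    k_min = 10L, k_max = 450L, k_step = 10L,
    merge_ratio = 0.9,
    plateau_epsilon = 0.01,
    iterations = 10L,
    quant_levels = c(8L, 16L, 32L, 64L),
    directions = c(0, 45, 90, 135),
    otsu_channels = 4L,
    rf_trees = 5L,
    cv_folds = 5L,
    train_fraction = 0.8,
    seed = 1L))
}

config_fields <- function() {
  c("similarity_threshold", "background_threshold", "annotation_threshold",
    "k_min", "k_max", "k_step", "merge_ratio", "plateau_epsilon",
    "iterations", "quant_levels", "directions", "otsu_channels", "rf_trees",
    "cv_folds", "train_fraction", "seed")
}

#' Validate a pipeline configuration
#'
#' Checks every field's type and range and rejects unknown keys.
#'
#' @param config Named list.
#' @return The validated `pipeline_config` (invisibly usable in place).
#' @export
validate_config <- function(config) {
  config <- unclass(config)
  unknown <- setdiff(names(config), config_fields())
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  missing <- setdiff(config_fields(), names(config))
  if (length(missing)) stop("missing config keys: ",
                            paste(missing, collapse = ", "))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  stopifnot(
    num1(config$similarity_threshold),
    config$similarity_threshold > -1, config$similarity_threshold <= 1,
    num1(config$background_threshold), config$background_threshold >= 0,
    num1(config$annotation_threshold),
    config$annotation_threshold > 0, config$annotation_threshold <= 1,
    num1(config$k_min), num1(config$k_max), num1(config$k_step),
    config$k_min >= 1, config$k_max >= config$k_min, config$k_step >= 1,
    num1(config$merge_ratio), config$merge_ratio > 0, config$merge_ratio <= 1,
    num1(config$plateau_epsilon), config$plateau_epsilon >= 0,
    num1(config$iterations), config$iterations >= 1,
    is.numeric(config$quant_levels), all(config$quant_levels >= 2),
    is.numeric(config$directions),
    all(config$directions %in% c(0, 45, 90, 135)),
    num1(config$otsu_channels), config$otsu_channels == 4,
    num1(config$rf_trees), config$rf_trees >= 1,
    num1(config$cv_folds), config$cv_folds >= 2,
    num1(config$train_fraction),
    config$train_fraction > 0, config$train_fraction < 1,
    num1(config$seed))
  structure(config, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file written by [save_config()] (or hand-edited).
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("k_min", "k_max", "k_step", "iterations", "quant_levels",
              "otsu_channels", "rf_trees", "cv_folds", "seed"))
    if (!is.null(raw[[f]])) raw[[f]] <- as.integer(raw[[f]])
  validate_config(raw)
}

#' Write a pipeline configuration to a YAML file
#'
#' Round-trips losslessly through [load_config()].
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_k_grid <- function(config) {
  seq(config$k_min, config$k_max, config$k_step)
}

# JSON-lines run log; path = NULL disables
log_stage <- function(path, stage, ...) {
  if (is.null(path)) return(invisible())
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = path,
      append = TRUE, sep = "")
  invisible()
}
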