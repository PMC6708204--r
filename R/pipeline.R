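#' End-to-end segmentation of one slice
#'
#' Runs the full pipeline on a slice: midline alignment, (TAR, TC)
#' descriptor, K prediction, SLIC0 superpixels, background removal,
#' feature extraction, SVM classification, and mask assembly. If a ground
#' truth is supplied the Dice / Hausdorff / sensitivity / specificity
#' metrics are computed as well. Deterministic for fixed inputs and
#' config. An all-background image yields an empty mask with a warning.
#'
#' @param image Intensity matrix or a path readable by [read_slice()].
#' @param k_model A `k_model` or a path to its JSON.
#' @param svm_model An `svm_model` or a path to its JSON.
#' @param config A `pipeline_config` (default [default_config()]).
#' @param gt Optional ground-truth mask (matrix or path).
#' @param out_mask Optional path: the mask is written there as 16-bit PNG.
#' @param log_path Optional path for a JSON-lines stage log.
#' @return List: `mask`, `k`, `descriptor`, `superpixels`, `retained`,
#'   `predictions`, and `metrics` (when `gt` is given).
#' @export
cmd_segment <- function(image, k_model, svm_model, config = default_config(),
                        gt = NULL, out_mask = NULL, log_path = NULL) {
  config <- validate_config(config)
  if (is.character(image)) image <- read_slice(image)
  if (is.character(k_model)) k_model <- load_k_model(k_model)
  if (is.character(svm_model)) svm_model <- load_svm_model(svm_model)
  if (is.character(gt)) gt <- read_mask(gt)

  if (!any(image >= config$background_threshold)) {
    warning("all-background image: returning an empty mask")
    mask <- matrix(0L, nrow(image), ncol(image))
    log_stage(log_path, "segment", status = "all_background")
    if (!is.null(out_mask)) write_mask(mask, out_mask)
    return(list(mask = mask, k = NA_integer_, descriptor = NULL,
                metrics = if (!is.null(gt)) evaluate_masks(mask, gt)))
  }

  desc <- tumor_descriptor(image, config$similarity_threshold)
  log_stage(log_path, "descriptor", tar = desc$tar, tc = desc$tc,
            shift = desc$alignment$shift, rotation = desc$alignment$rotation)

  k <- predict_k(k_model, desc)
  log_stage(log_path, "predict_k", k = k)

  sp <- run_slic0(image, k, iterations = config$iterations)
  log_stage(log_path, "slic0", k_requested = k, count = sp$count)

  retained <- remove_background_superpixels(image, sp,
                                            config$background_threshold)
  background_ids <- setdiff(seq_len(sp$count) - 1L, retained)
  log_stage(log_path, "background_removal", retained = length(retained),
            removed = length(background_ids))

  feats <- extract_feature_table(image, sp, retained,
                                 levels = config$quant_levels,
                                 directions = config$directions,
                                 fg_threshold = config$background_threshold)
  log_stage(log_path, "features", rows = nrow(feats), cols = ncol(feats) - 1L)

  pred <- predict_superpixels(svm_model, feats)
  mask <- assemble_segmentation(sp, pred, background_ids)
  log_stage(log_path, "assemble", tumor_superpixels = sum(pred == "tumor"),
            mask_pixels = sum(mask))

  if (!is.null(out_mask)) write_mask(mask, out_mask)
  out <- list(mask = mask, k = k, descriptor = desc, superpixels = sp,
              retained = retained, predictions = pred)
  if (!is.null(gt)) {
    out$metrics <- evaluate_masks(mask, gt)
    log_stage(log_path, "evaluate", dice = out$metrics$dice,
              hd = out$metrics$hd)
  }
  out
}

#' Train the K model and the SVM on a set of (slice, mask) pairs
#'
#' Splits the pairs into train/test (seed-reproducible, stratified by
#' `grade` when given), then on the training portion: labels the best K
#' per slice by grid search against the ground truth and trains the
#' random-forest K model; generates SLIC0 superpixels at each slice's
#' labeled best K, annotates them from the ground truth, extracts the
#' 69-feature table, and trains the SVM.
#'
#' @param pairs Either a data frame with columns `slice` and `mask`
#'   (paths, plus optional `grade`), or a list of `list(image=, mask=)`
#'   matrices.
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory: writes `k_model.json`,
#'   `svm_model.json`, `split.tsv` and `k_samples.tsv`.
#' @param log_path Optional path for a JSON-lines stage log.
#' @return List: `k_model`, `svm_model`, `split` (manifest data frame
#'   with a `role` column), `k_samples` (per-slice TAR/TC/k_best).
#' @export
cmd_train_all <- function(pairs, config = default_config(), out_dir = NULL,
                          log_path = NULL) {
  config <- validate_config(config)
  items <- normalize_pairs(pairs)
  n <- length(items)
  if (n < 10L) stop("need at least 10 (slice, mask) pairs")

  grade <- vapply(items, function(it) it$grade, character(1))
  role <- with_seed(config$seed, split_train_test(grade, config$train_fraction))
  train_ix <- which(role == "train")
  log_stage(log_path, "split", n = n, n_train = length(train_ix))

  k_samples <- do.call(rbind, lapply(train_ix, function(i) {
    it <- items[[i]]
    desc <- tumor_descriptor(it$image, config$similarity_threshold)
    k_best <- label_best_k(it$image, it$mask,
                           k_grid = config_k_grid(config),
                           merge_ratio = config$merge_ratio,
                           plateau_epsilon = config$plateau_epsilon,
                           iterations = config$iterations)
    data.frame(sample = i, tar = desc$tar, tc = desc$tc,
               k_best = as.integer(k_best))
  }))
  log_stage(log_path, "label_best_k", n = nrow(k_samples))

  k_model <- train_k_model(k_samples, seed = config$seed,
                           trees = config$rf_trees)

  feature_rows <- lapply(train_ix, function(i) {
    it <- items[[i]]
    sp <- run_slic0(it$image, k_samples$k_best[k_samples$sample == i],
                    iterations = config$iterations)
    retained <- remove_background_superpixels(it$image, sp,
                                              config$background_threshold)
    ann <- annotate_superpixels(sp, it$mask, config$annotation_threshold)
    feats <- extract_feature_table(it$image, sp, retained,
                                   levels = config$quant_levels,
                                   directions = config$directions,
                                   fg_threshold = config$background_threshold)
    list(features = feats, labels = ann$label[match(feats$id, ann$id)])
  })
  features <- do.call(rbind, lapply(feature_rows, `[[`, "features"))
  labels <- unlist(lapply(feature_rows, `[[`, "labels"))
  log_stage(log_path, "training_set", rows = nrow(features),
            tumor = sum(labels == "tumor"))

  svm_model <- train_svm(features, labels, seed = config$seed,
                         folds = config$cv_folds)
  log_stage(log_path, "train_svm", cost = svm_model$cost,
            gamma = svm_model$gamma)

  split <- data.frame(sample = seq_len(n), grade = grade, role = role)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_k_model(k_model, file.path(out_dir, "k_model.json"))
    save_svm_model(svm_model, file.path(out_dir, "svm_model.json"))
    write.table(split, file.path(out_dir, "split.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(k_samples, file.path(out_dir, "k_samples.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  list(k_model = k_model, svm_model = svm_model, split = split,
       k_samples = k_samples)
}

normalize_pairs <- function(pairs) {
  if (is.data.frame(pairs)) {
    lapply(seq_len(nrow(pairs)), function(i)
      list(image = read_slice(pairs$slice[i]),
           mask = read_mask(pairs$mask[i]),
           grade = if ("grade" %in% names(pairs))
             as.character(pairs$grade[i]) else "all"))
  } else {
    lapply(pairs, function(p)
      list(image = p$image, mask = p$mask,
           grade = if (!is.null(p$grade)) as.character(p$grade) else "all"))
  }
}

# stratified, seed-reproducible train/test split (call under with_seed)
split_train_test <- function(grade, train_fraction) {
  role <- character(length(grade))
  for (g in unique(grade)) {
    ix <- sample(which(grade == g))
    n_train <- round(length(ix) * train_fraction)
    role[ix[seq_len(n_train)]] <- "train"
    if (n_train < length(ix)) role[ix[(n_train + 1L):length(ix)]] <- "test"
  }
  role
}

#' Evaluate predicted masks against ground truth as a cohort table
#'
#' @param pred_masks List of predicted masks (or paths).
#' @param gt_masks List of ground-truth masks (or paths), same length.
#' @param group Optional per-case group labels (e.g. grade).
#' @return The [summarize_cohort()] table; per-case metrics are attached
#'   as attribute `"cases"`.
#' @export
cmd_evaluate <- function(pred_masks, gt_masks, group = NULL) {
  stopifnot(length(pred_masks) == length(gt_masks))
  metrics <- do.call(rbind, lapply(seq_along(pred_masks), function(i) {
    p <- pred_masks[[i]]; g <- gt_masks[[i]]
    if (is.character(p)) p <- read_mask(p)
    if (is.character(g)) g <- read_mask(g)
    evaluate_masks(p, g)
  }))
  out <- summarize_cohort(metrics, group)
  attr(out, "cases") <- metrics
  out
}
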