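#' Annotate superpixels from ground truth
#'
#' A superpixel's overlap is the fraction of its own pixels lying inside
#' the ground-truth tumor mask; it is labeled tumor when the overlap
#' reaches the annotation threshold. (Literal Dice between a small
#' superpixel and the whole tumor would penalize size; the proportion of
#' the superpixel covered is what decides membership.)
#'
#' @param sp A `superpixel_map`.
#' @param gt Binary ground-truth mask, same lattice.
#' @param threshold Overlap fraction at which a superpixel becomes tumor
#'   (default 0.5; labeled tumor iff `overlap >= threshold`).
#' @return Data frame: `id` (0-based), `overlap`, `label` (factor
#'   `non_tumor` / `tumor`).
#' @export
annotate_superpixels <- function(sp, gt, threshold = 0.5) {
  assert_mask(gt, sp$labels)
  sizes <- tabulate(sp$labels + 1L, nbins = sp$count)
  inside <- tabulate(sp$labels[gt != 0] + 1L, nbins = sp$count)
  overlap <- inside / sizes
  data.frame(id = seq_len(sp$count) - 1L, overlap = overlap,
             label = factor(ifelse(overlap >= threshold, "tumor", "non_tumor"),
                            levels = c("non_tumor", "tumor")))
}

#' Train the superpixel SVM classifier
#'
#' Features are standardized (z-score with training statistics); the RBF
#' kernel parameters (C, gamma) are selected on a deterministic 7x7
#' logarithmic grid (C in 10^[-3, 3], gamma in 10^[-4, 1]) by maximizing
#' mean 5-fold cross-validated balanced accuracy; the final model is refit
#' on all training data with class weights inversely proportional to class
#' frequency. Deterministic given the seed.
#'
#' @param features Numeric matrix or data frame of features (rows =
#'   superpixels; an `id` column, if present, is dropped).
#' @param labels Factor (or vector coercible to one) with two classes;
#'   conventionally `non_tumor` / `tumor`.
#' @param seed Integer seed (controls the CV fold assignment).
#' @param folds Number of CV folds (default 5).
#' @param cost_grid,gamma_grid Candidate values for C and gamma.
#' @return List of class `svm_model`: `center`/`scale` standardization
#'   vectors, `cost`, `gamma`, the fitted e1071 model, class levels, and
#'   the CV score table.
#' @export
train_svm <- function(features, labels, seed = 1L, folds = 5L,
                      cost_grid = 10^seq(-3, 3, length.out = 7),
                      gamma_grid = 10^seq(-4, 1, length.out = 7)) {
  X <- as_feature_matrix(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L) stop("both classes must be present")
  if (nrow(X) < 20L) stop("need at least 20 training samples")
  if (nrow(X) != length(y)) stop("features and labels disagree in length")

  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ == 0] <- 1  # constant columns carry no information
  Z <- sweep(sweep(X, 2, center), 2, scale_, "/")

  cw <- nrow(X) / (2 * table(y))
  class_weights <- stats::setNames(as.numeric(cw), names(cw))

  fold_id <- with_seed(seed, stratified_folds(y, folds))
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f; te <- !tr
      if (nlevels(droplevels(y[tr])) < 2L) return(NA_real_)
      fit <- e1071::svm(Z[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g],
                        class.weights = class_weights, scale = FALSE)
      balanced_accuracy(y[te], predict(fit, Z[te, , drop = FALSE]))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores)  # first maximum: deterministic on ties

  fit <- e1071::svm(Z, y, kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best], class.weights = class_weights,
                    scale = FALSE)
  structure(list(center = center, scale = scale_, cost = grid$cost[best],
                 gamma = grid$gamma[best], fit = fit, levels = levels(y),
                 cv = cbind(grid, balanced_accuracy = scores),
                 training_meta = list(seed = seed, folds = folds)),
            class = "svm_model")
}

balanced_accuracy <- function(truth, pred) {
  mean(vapply(levels(truth), function(l) {
    n <- sum(truth == l)
    if (n == 0) NA_real_ else sum(pred == l & truth == l) / n
  }, numeric(1)), na.rm = TRUE)
}

stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (l in levels(y)) {
    ix <- sample(which(y == l))
    id[ix] <- rep_len(seq_len(folds), length(ix))
  }
  id
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    features <- features[, setdiff(names(features), "id"), drop = FALSE]
    features <- as.matrix(features)
  }
  storage.mode(features) <- "double"
  features
}

#' Predict tumor / non-tumor for superpixel feature rows
#'
#' Standardizes with the stored training statistics and applies the SVM
#' decision function. Deterministic.
#'
#' @param model An `svm_model`.
#' @param features Feature matrix or data frame with the same columns as
#'   at training time (an `id` column, if present, names the output).
#' @return Factor of predicted labels, named by `id` when available.
#' @export
predict_superpixels <- function(model, features) {
  ids <- if (is.data.frame(features) && "id" %in% names(features))
    features$id else NULL
  X <- as_feature_matrix(features)
  if (ncol(X) != length(model$center))
    stop("feature columns do not match the trained model")
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  pred <- if (!is.null(model$fit)) {
    predict(model$fit, Z)
  } else {
    d <- svm_decision_values(model, Z)
    factor(ifelse(d > 0, model$decision_label, model$other_label),
           levels = model$levels)
  }
  if (!is.null(ids)) names(pred) <- ids
  pred
}

#' RBF decision values by explicit kernel expansion
#'
#' `f(x) = sum_i coef_i exp(-gamma ||sv_i - x||^2) - rho`, evaluated from
#' the stored support vectors. Used for JSON-portable models and as the
#' reference for the decision function.
#'
#' @param model An `svm_model` (fitted or loaded from JSON).
#' @param Z Standardized feature matrix.
#' @return Numeric decision values; positive values vote for the class in
#'   `model$decision_label`.
#' @export
svm_decision_values <- function(model, Z) {
  sv <- if (!is.null(model$fit)) model$fit$SV else model$SV
  coefs <- if (!is.null(model$fit)) model$fit$coefs[, 1] else model$coefs
  rho <- if (!is.null(model$fit)) model$fit$rho else model$rho
  g <- model$gamma
  # ||z - sv||^2 = |z|^2 + |sv|^2 - 2 z.sv, without forming explicit pairs
  d2 <- outer(rowSums(Z^2), rowSums(sv^2), "+") - 2 * tcrossprod(Z, sv)
  k <- exp(-g * pmax(d2, 0))
  as.numeric(k %*% coefs - rho)
}

#' Assemble the final segmentation mask
#'
#' The mask is the union of tumor-predicted superpixels; superpixels
#' removed as background are forced to 0 regardless of prediction.
#'
#' @param sp A `superpixel_map`.
#' @param predictions Factor/character of predicted labels named by
#'   0-based superpixel id (as from [predict_superpixels()]).
#' @param background_ids Integer vector of background superpixel ids.
#' @return Binary mask matrix.
#' @export
assemble_segmentation <- function(sp, predictions, background_ids = integer(0)) {
  retained <- setdiff(seq_len(sp$count) - 1L, as.integer(background_ids))
  ids <- as.integer(names(predictions))
  if (is.null(names(predictions)) || !all(retained %in% ids))
    stop("every retained superpixel needs a prediction")
  tumor_ids <- ids[as.character(predictions) == "tumor"]
  tumor_ids <- setdiff(tumor_ids, as.integer(background_ids))
  matrix(as.integer(sp$labels %in% tumor_ids), nrow(sp$labels), ncol(sp$labels))
}
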