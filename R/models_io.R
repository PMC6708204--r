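#' Persist a K model as portable JSON
#'
#' The forest is flattened to its individual tree structures (daughters,
#' split variables, split points, leaf predictions), so a saved model can
#' be reloaded and used for prediction without the randomForest object.
#'
#' @param model A `k_model`.
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
save_k_model <- function(model, path) {
  stopifnot(inherits(model, "k_model"))
  trees <- lapply(seq_len(model$forest$ntree), function(k) {
    tr <- randomForest::getTree(model$forest, k, labelVar = FALSE)
    list(left = tr[, "left daughter"], right = tr[, "right daughter"],
         var = tr[, "split var"], point = tr[, "split point"],
         status = tr[, "status"], prediction = tr[, "prediction"])
  })
  jsonlite::write_json(
    list(type = "k_model", predictors = c("tar", "tc"),
         k_range = model$k_range, trees = trees,
         training_meta = model$training_meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a K model saved by [save_k_model()]
#'
#' @param path `.json` path.
#' @return A `k_model` usable with [predict_k()].
#' @export
load_k_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(raw$type, "k_model"))
  trees <- raw$trees
  if (is.data.frame(trees))  # simplifyVector collapses the tree list
    trees <- lapply(seq_len(nrow(trees)), function(i)
      lapply(trees, function(col) col[[i]]))
  structure(list(forest = NULL, trees = trees,
                 k_range = as.integer(raw$k_range),
                 training_meta = raw$training_meta),
            class = "k_model")
}

# mean over trees; each tree: nodes 1-based, terminal status == -1,
# x[splitvar] <= splitpoint goes left
predict_forest_json <- function(trees, newdata) {
  X <- as.matrix(newdata[, c("tar", "tc"), drop = FALSE])
  vapply(seq_len(nrow(X)), function(i) {
    mean(vapply(trees, function(tr) {
      node <- 1L
      while (tr$status[node] != -1) {
        v <- tr$var[node]
        node <- if (X[i, v] <= tr$point[node]) tr$left[node] else tr$right[node]
      }
      tr$prediction[node]
    }, numeric(1)))
  }, numeric(1))
}

#' Persist an SVM model as portable JSON
#'
#' Stores the standardization statistics, kernel parameters, support
#' vectors, coefficients and bias — everything needed to evaluate the
#' decision function by explicit kernel expansion.
#'
#' @param model An `svm_model`.
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
save_svm_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  fit <- model$fit
  # class voted for by positive decision values
  decision_label <- sub("/.*$", "", colnames(fit$decision.values))
  other_label <- setdiff(model$levels, decision_label)
  jsonlite::write_json(
    list(type = "svm_model", center = model$center, scale = model$scale,
         cost = model$cost, gamma = model$gamma, levels = model$levels,
         decision_label = decision_label, other_label = other_label,
         SV = fit$SV, coefs = as.numeric(fit$coefs[, 1]), rho = fit$rho,
         training_meta = model$training_meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an SVM model saved by [save_svm_model()]
#'
#' @param path `.json` path.
#' @return An `svm_model` usable with [predict_superpixels()] (decision
#'   values are computed by kernel expansion).
#' @export
load_svm_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(raw$type, "svm_model"))
  structure(list(center = raw$center, scale = raw$scale, cost = raw$cost,
                 gamma = raw$gamma, levels = raw$levels,
                 decision_label = raw$decision_label,
                 other_label = raw$other_label,
                 SV = as.matrix(raw$SV), coefs = raw$coefs, rho = raw$rho,
                 fit = NULL, training_meta = raw$training_meta),
            class = "svm_model")
}
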