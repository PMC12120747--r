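#' Train the per-organoid High/Low-CEA random forest
#'
#' Fits a random forest on the three morphometric features
#' (`area_um2`, `perimeter_um`, `circularity`) against the binary CEA
#' class. Defaults: 100 trees, unlimited depth, sqrt(p) candidate features
#' per split, class weights inversely proportional to class frequency
#' (balanced), fixed seed. Trees are scale-invariant, so no feature
#' scaling is applied.
#'
#' @param cohort Feature table with the three feature columns and
#'   `cea_class` in `{"High", "Low"}`, both classes present.
#' @param n_trees Number of trees.
#' @param mtry Candidate features per split; default `floor(sqrt(p))`.
#' @param nodesize Minimum terminal-node size (1 = grow to purity).
#' @param seed Training seed; fit and predictions are deterministic
#'   given it.
#' @return An `organovote_model` wrapping the fit plus metadata
#'   (hyperparameters, seed, feature order, class order).
#' @export
train_classifier <- function(cohort, n_trees = 100, mtry = NULL,
                             nodesize = 1, seed = 0L) {
  features <- c("area_um2", "perimeter_um", "circularity")
  missing <- setdiff(c(features, "cea_class"), names(cohort))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  x <- as.data.frame(cohort)[, features]
  if (anyNA(x)) stop("missing feature values")
  y <- factor(cohort$cea_class, levels = c("High", "Low"))
  if (anyNA(y)) stop("cea_class must be High or Low")
  if (length(unique(y)) < 2) stop("training table must contain both classes")
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(length(features))))

  classwt <- 1 / prop.table(table(y))
  fit <- with_seed(as.integer(seed),
    randomForest::randomForest(
      x = x, y = y, ntree = n_trees, mtry = mtry,
      nodesize = nodesize, classwt = as.numeric(classwt)
    )
  )
  structure(
    list(fit = fit,
         features = features,
         classes = c("High", "Low"),
         hyper = list(n_trees = n_trees, mtry = mtry, nodesize = nodesize,
                      class_weights = as.numeric(classwt)),
         seed = as.integer(seed),
         version = as.character(utils::packageVersion("organovote"))),
    class = "organovote_model"
  )
}

#' Predict per-organoid classes
#'
#' @param object An `organovote_model`.
#' @param newdata Feature table containing the model's feature columns.
#' @param ... Unused.
#' @return Factor of `"High"` / `"Low"` calls, one per row.
#' @export
predict.organovote_model <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)[, object$features, drop = FALSE]
  if (anyNA(x)) stop("missing feature values in newdata")
  # decide from the tree-vote matrix with a fixed tie-break (first class),
  # rather than predict()'s randomized tie-breaking: predictions must be
  # deterministic and row-order invariant given a fitted model
  votes <- predict(object$fit, x, type = "vote", norm.votes = FALSE)
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' Evaluate a fitted classifier on a labeled table
#'
#' Tallies per-organoid predictions into a confusion summary with
#' High-CEA as the positive class, and reports per-class accuracy
#' (recall): correct / total within each true class.
#'
#' @param model An `organovote_model`.
#' @param cohort Labeled feature table.
#' @return A `confusion_summary`: list with `counts` (TP, FN, FP, TN),
#'   `accuracy_high`, `accuracy_low`, `accuracy_overall`, `n`.
#' @export
evaluate_classifier <- function(model, cohort) {
  if (!"cea_class" %in% names(cohort) || anyNA(cohort$cea_class)) {
    stop("evaluation requires labeled rows")
  }
  truth <- factor(cohort$cea_class, levels = c("High", "Low"))
  if (anyNA(truth)) stop("cea_class must be High or Low")
  pred <- predict(model, cohort)
  confusion_summary(truth, pred)
}

#' Build a confusion summary from truth and predictions
#'
#' @param truth,pred Factors (or characters) of `"High"` / `"Low"` calls.
#' @return A `confusion_summary` object.
#' @export
confusion_summary <- function(truth, pred) {
  truth <- factor(truth, levels = c("High", "Low"))
  pred <- factor(pred, levels = c("High", "Low"))
  tp <- sum(truth == "High" & pred == "High")
  fn <- sum(truth == "High" & pred == "Low")
  fp <- sum(truth == "Low" & pred == "High")
  tn <- sum(truth == "Low" & pred == "Low")
  n_high <- tp + fn
  n_low <- fp + tn
  structure(
    list(counts = c(TP = tp, FN = fn, FP = fp, TN = tn),
         accuracy_high = if (n_high > 0) tp / n_high else NA_real_,
         accuracy_low = if (n_low > 0) tn / n_low else NA_real_,
         accuracy_overall = (tp + tn) / (n_high + n_low),
         n = n_high + n_low),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("Per-organoid confusion summary (positive class: High-CEA)\n")
  cat(sprintf("  n = %d | TP %d  FN %d  FP %d  TN %d\n",
              x$n, x$counts["TP"], x$counts["FN"],
              x$counts["FP"], x$counts["TN"]))
  cat(sprintf("  accuracy  High: %.1f%%   Low: %.1f%%   overall: %.1f%%\n",
              100 * x$accuracy_high, 100 * x$accuracy_low,
              100 * x$accuracy_overall))
  invisible(x)
}

#' Save / load a fitted model with a JSON metadata sidecar
#'
#' The model is serialized as an RDS artifact; a `<path>.json` sidecar
#' records hyperparameters, seed, feature order and package version so a
#' run can be audited without deserializing the model.
#'
#' @param model An `organovote_model`.
#' @param path Output path for the binary artifact.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "organovote_model"))
  saveRDS(model, path)
  meta <- list(version = model$version, seed = model$seed,
               features = model$features, classes = model$classes,
               hyper = model$hyper)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "organovote_model")) stop("not an organovote model artifact")
  model
}
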