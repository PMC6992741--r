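# The SVM meta-classifier: scaling, training, prediction, cross-validation
# and metric-panel evaluation of external tools' raw calls.

#' @importFrom e1071 svm
NULL

.as_label_factor <- function(y) factor(as.character(y),
                                       levels = c("negative", "positive"))

#' Min-max feature scaling
#'
#' Maps every feature linearly onto `[0, 1]` using its training range;
#' constant features map to 0. The returned parameters can be re-applied to
#' new data with [apply_scaling()], which clips to `[0, 1]` so test values
#' outside the training range cannot leave the unit interval.
#'
#' @param x Numeric matrix (finite values).
#' @return List with `x` (the scaled matrix) and `params` (per-feature
#'   `min` and `range`).
#' @export
scale_features <- function(x) {
  if (any(!is.finite(x))) stop("non-finite values in feature matrix")
  mins <- apply(x, 2, min)
  rng <- apply(x, 2, max) - mins
  params <- list(min = mins, range = rng, features = colnames(x))
  list(x = apply_scaling(params, x), params = params)
}

#' @rdname scale_features
#' @param params Scaling parameters from [scale_features()].
#' @export
apply_scaling <- function(params, x) {
  if (any(!is.finite(x))) stop("non-finite values in feature matrix")
  sc <- sweep(x, 2, params$min, "-")
  safe_rng <- ifelse(params$range == 0, 1, params$range)
  sc <- sweep(sc, 2, safe_rng, "/")
  sc[, params$range == 0] <- 0
  pmin(pmax(sc, 0), 1)  # argument order keeps the matrix dim
}

#' SVM configuration
#'
#' Defaults: soft-margin RBF kernel, cost 1, kernel width
#' `gamma = 1/ncol(x)`. These are the standard LIBSVM defaults; no grid
#' search is run by default so results are exactly reproducible.
#'
#' @param kernel Kernel name passed to [e1071::svm()].
#' @param cost Soft-margin cost C.
#' @param gamma RBF width; `NULL` means `1/number of features`.
#' @return A config list.
#' @export
svm_config <- function(kernel = "radial", cost = 1, gamma = NULL) {
  list(kernel = kernel, cost = cost, gamma = gamma)
}

#' Train the SVM meta-classifier
#'
#' Fits a soft-margin kernel SVM on min-max-scaled features. The decision
#' rule is the classifier's sign; no probability calibration is applied.
#'
#' @param x Numeric feature matrix with named columns.
#' @param y Labels (`"positive"`/`"negative"`), both classes present.
#' @param config See [svm_config()].
#' @param seed Integer seed (the fit itself is deterministic; the seed is
#'   stored and set for reproducibility of any stochastic kernel setup).
#' @return An object of class `meta_model`: the fitted classifier plus the
#'   scaling parameters, ordered feature subset and training config.
#' @export
train_meta_model <- function(x, y, config = svm_config(), seed = 1) {
  yf <- .as_label_factor(y)
  if (length(unique(yf)) < 2 || any(table(yf) == 0))
    stop("both classes must be present in the training labels")
  sc <- scale_features(x)
  gamma <- if (is.null(config$gamma)) 1 / ncol(x) else config$gamma
  fit <- withr::with_seed(seed,
    e1071::svm(sc$x, yf, kernel = config$kernel, cost = config$cost,
               gamma = gamma, scale = FALSE))
  structure(list(fit = fit, scaling = sc$params, features = colnames(x),
                 config = config, gamma = gamma, seed = seed),
            class = "meta_model")
}

#' Predict with a trained meta-classifier
#'
#' @param object A `meta_model`.
#' @param newdata Feature matrix containing at least the model's stored
#'   feature subset (extra columns are ignored; order is restored from the
#'   model).
#' @param ... Unused.
#' @return Character vector of `"positive"`/`"negative"` calls, one per row.
#' @export
predict.meta_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing) > 0)
    stop("missing features: ", paste(missing, collapse = ", "))
  if (nrow(newdata) == 0) return(character(0))
  xs <- apply_scaling(object$scaling,
                      newdata[, object$features, drop = FALSE])
  as.character(stats::predict(object$fit, xs))
}

#' Stratified k-fold cross-validation of the meta-classifier
#'
#' Each record is predicted exactly once, out of fold; per-fold confusion
#' counts are summed and the pooled counts evaluated as one metric panel
#' (pooling, rather than averaging per-fold metrics, keeps the panel
#' well-defined even when single folds are degenerate).
#'
#' @param x Feature matrix.
#' @param y Labels.
#' @param k Folds.
#' @param seed Seed for the fold assignment.
#' @param config See [svm_config()].
#' @param folds Optional precomputed fold vector (overrides `k`/`seed`
#'   for the assignment; `k` is then taken from it).
#' @return An object of class `cv_result`: list with `fold_counts`
#'   (list of [confusion_counts()]), `counts` (pooled), `panel` (pooled
#'   [panel_from_counts()] panel), `predictions` and `folds`.
#' @export
cross_validate <- function(x, y, k = 10, seed = 1, config = svm_config(),
                           folds = NULL) {
  if (is.null(folds)) folds <- stratified_kfold(y, k, seed)
  k <- max(folds)
  yf <- as.character(y)
  pred <- character(length(yf))
  fold_counts <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- train_meta_model(x[!test, , drop = FALSE], yf[!test],
                              config = config, seed = seed)
    pred[test] <- predict(model, x[test, , drop = FALSE])
    fold_counts[[f]] <- confusion_counts(
      tp = sum(pred[test] == "positive" & yf[test] == "positive"),
      fn = sum(pred[test] == "negative" & yf[test] == "positive"),
      fp = sum(pred[test] == "positive" & yf[test] == "negative"),
      tn = sum(pred[test] == "negative" & yf[test] == "negative"))
  }
  pooled <- Reduce(`+`, lapply(fold_counts, unclass))
  counts <- confusion_counts(pooled[["tp"]], pooled[["fn"]], pooled[["fp"]],
                             pooled[["tn"]])
  structure(list(fold_counts = fold_counts, counts = counts,
                 panel = panel_from_counts(counts), predictions = pred,
                 folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(length(x$fold_counts), "-fold cross-validation, pooled panel:\n",
      sep = "")
  print(x$panel)
  invisible(x)
}

#' Evaluate an upstream tool's raw predictions as a metric panel
#'
#' Compares a tool's (possibly partial) binding calls against labelled
#' truth. Tools rarely emit a call for every pair; the missing-prediction
#' policy controls how unpredicted pairs enter the confusion counts:
#' `missing_as_negative` (default) counts them as non-binding calls —
#' silence is a miss on a true interaction; `exclude_missing` drops them
#' from all counts, which can flatter a low-coverage tool. Both policies
#' are worth reporting side by side when coverage differs across tools.
#'
#' @param tool_predictions Data.frame with `mirna_id`, `target_id`, `call`
#'   (`"positive"`/`"negative"`); a partial map over the truth pairs.
#' @param truth Data.frame with `mirna_id`, `target_id`, `label`.
#' @param policy `"missing_as_negative"` or `"exclude_missing"`.
#' @return A `metric_panel` with the confusion counts attached.
#' @export
evaluate_tool_panel <- function(tool_predictions, truth,
                                policy = c("missing_as_negative",
                                           "exclude_missing")) {
  policy <- match.arg(policy)
  if (nrow(truth) == 0) stop("empty truth table")
  tkey <- paste(truth$mirna_id, truth$target_id, sep = "|")
  pkey <- paste(tool_predictions$mirna_id, tool_predictions$target_id,
                sep = "|")
  extra <- setdiff(pkey, tkey)
  if (length(extra) > 0)
    stop("prediction for pair(s) absent from truth: ",
         paste(utils::head(extra, 3), collapse = ", "))
  call <- stats::setNames(as.character(tool_predictions$call), pkey)[tkey]
  keep <- if (policy == "exclude_missing") !is.na(call)
          else rep(TRUE, length(call))
  call[is.na(call)] <- "negative"
  lab <- as.character(truth$label)[keep]; call <- call[keep]
  counts <- confusion_counts(
    tp = sum(call == "positive" & lab == "positive"),
    fn = sum(call == "negative" & lab == "positive"),
    fp = sum(call == "positive" & lab == "negative"),
    tn = sum(call == "negative" & lab == "negative"))
  panel_from_counts(counts)
}

#' Extract a tool's binding calls from the interchange table
#'
#' @param tool_table Long-format tool output table.
#' @param tool One of [supported_tools()].
#' @return Data.frame `mirna_id`, `target_id`, `call`.
#' @export
tool_calls_from_table <- function(tool_table, tool) {
  rows <- tool_table[tool_table$tool == tool & tool_table$field == "call", ,
                     drop = FALSE]
  rows <- rows[!duplicated(paste(rows$mirna_id, rows$target_id, sep = "|")), ,
               drop = FALSE]
  data.frame(mirna_id = rows$mirna_id, target_id = rows$target_id,
             call = ifelse(suppressWarnings(as.numeric(rows$value)) != 0,
                           "positive", "negative"),
             stringsAsFactors = FALSE)
}
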