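# mRMR feature ranking under the mutual-information-quotient (MIQ) scheme
# and CHL-driven incremental feature selection (IFS).

# Discretize a numeric feature for MI estimation. Binary/indicator columns
# (all values in {0,1}) are used as-is; other columns are binned by
# equal-frequency quantile cuts.
.discretize <- function(x, bins = 10) {
  ux <- unique(x)
  if (all(ux %in% c(0, 1)) || length(ux) <= 2) return(factor(x))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

.mi_discrete <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  pe <- outer(pa, pb)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / pe[nz]))
}

#' Mutual information between a feature and the class labels
#'
#' Estimates MI (in bits) from the empirical joint distribution after
#' equal-frequency discretization of the feature into `bins` bins.
#' Binary/indicator features bypass binning. The estimator is the plug-in
#' estimator; it is non-negative by construction and biased upward at small
#' sample sizes, which is immaterial for ranking purposes.
#'
#' @param x Numeric feature column.
#' @param y Class labels, at least two distinct values.
#' @param bins Number of equal-frequency bins for continuous features
#'   (default 10).
#' @return Non-negative MI in bits.
#' @examples
#' y <- rep(c("positive", "negative"), 50)
#' mutual_information(as.numeric(y == "positive"), y)  # = H(y) = 1 bit
#' @export
mutual_information <- function(x, y, bins = 10) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2")
  if (length(unique(y)) < 2) stop("degenerate labels")
  .mi_discrete(.discretize(x, bins), factor(y))
}

#' mRMR feature ranking (MIQ scheme)
#'
#' Greedy minimum-redundancy-maximum-relevance ranking: the first feature
#' maximizes MI with the labels (relevance); each later feature maximizes
#' the quotient of its relevance over its redundancy, the mean MI with the
#' features already selected. Ties are broken by feature name so the
#' ranking is deterministic. A small floor on the redundancy denominator
#' keeps the quotient finite when a candidate shares no information with
#' the selected set.
#'
#' @param x Numeric feature matrix (columns named).
#' @param y Class labels.
#' @param bins Discretization bins, as in [mutual_information()].
#' @param epsilon Redundancy floor in bits (default `2^-20`).
#' @return An object of class `ranked_features`: data.frame with columns
#'   `rank`, `feature`, `relevance`, `redundancy`, `quotient`.
#' @export
mrmr_miq_rank <- function(x, y, bins = 10, epsilon = 2^-20) {
  if (is.null(colnames(x)) || ncol(x) < 2)
    stop("x must be a named matrix with at least 2 feature columns")
  if (length(unique(y)) < 2) stop("degenerate labels")
  feats <- colnames(x)
  disc <- lapply(feats, function(f) .discretize(x[, f], bins))
  names(disc) <- feats
  yf <- factor(y)
  relevance <- vapply(feats, function(f) .mi_discrete(disc[[f]], yf),
                      numeric(1))

  mi_cache <- new.env(parent = emptyenv())
  pair_mi <- function(a, b) {
    k <- paste(sort(c(a, b)), collapse = "\r")
    v <- mi_cache[[k]]
    if (is.null(v)) {
      v <- .mi_discrete(disc[[a]], disc[[b]])
      mi_cache[[k]] <- v
    }
    v
  }

  selected <- character(0)
  out <- vector("list", length(feats))
  remaining <- feats
  for (step in seq_along(feats)) {
    if (step == 1) {
      red <- stats::setNames(rep(0, length(remaining)), remaining)
      quot <- relevance[remaining]
    } else {
      red <- vapply(remaining, function(f)
        mean(vapply(selected, function(s) pair_mi(f, s), numeric(1))),
        numeric(1))
      quot <- relevance[remaining] / pmax(red, epsilon)
    }
    best <- sort(remaining[quot == max(quot)])[1]
    out[[step]] <- data.frame(rank = step, feature = best,
                              relevance = unname(relevance[best]),
                              redundancy = unname(red[best]),
                              quotient = unname(quot[best]),
                              stringsAsFactors = FALSE)
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  ranking <- do.call(rbind, out)
  class(ranking) <- c("ranked_features", "data.frame")
  ranking
}

#' Incremental feature selection driven by cross-validated CHL
#'
#' Walks the ranked feature list from the top, evaluating each prefix
#' (size 1, 2, ..., n) by k-fold cross-validated CHL index of the trainer,
#' and selects the smallest prefix attaining the maximum of the curve.
#' The same seeded fold assignment is reused for every prefix so curve
#' differences reflect the feature set only. A prefix on which the trainer
#' fails (or whose pooled CHL is undefined) is recorded as `NA` and
#' excluded from the argmax.
#'
#' @param x Feature matrix; columns must cover `ranked$feature`.
#' @param y Class labels.
#' @param ranked A `ranked_features` object from [mrmr_miq_rank()].
#' @param k Folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param config SVM configuration for the default trainer, see
#'   [svm_config()].
#' @param max_size Optional cap on the largest prefix evaluated (default:
#'   all features).
#' @return An object of class `ifs_result`: list with `curve` (data.frame
#'   `size`, `chl`), `selected` (character vector of chosen features) and
#'   `best_chl`.
#' @export
ifs_select <- function(x, y, ranked, k = 10, seed = 1, config = svm_config(),
                       max_size = NULL) {
  feats <- ranked$feature
  if (!all(feats %in% colnames(x)))
    stop("ranking refers to features absent from the matrix")
  n <- if (is.null(max_size)) length(feats) else min(max_size, length(feats))
  folds <- stratified_kfold(y, k, seed)
  chl <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    sub <- x[, feats[seq_len(s)], drop = FALSE]
    res <- tryCatch(
      cross_validate(sub, y, k = k, seed = seed, config = config,
                     folds = folds),
      error = function(e) NULL)
    if (!is.null(res)) chl[s] <- res$panel$chl
  }
  if (all(is.na(chl))) stop("IFS failed: no prefix produced a defined CHL")
  best <- which(chl == max(chl, na.rm = TRUE))[1]
  structure(list(curve = data.frame(size = seq_len(n), chl = chl),
                 selected = feats[seq_len(best)],
                 best_chl = chl[best]),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat("IFS: ", length(x$selected), " features selected, CV CHL = ",
      format_metric(x$best_chl), "\n", sep = "")
  invisible(x)
}

#' @export
plot.ifs_result <- function(x, ...) {
  plot(x$curve$size, x$curve$chl, type = "l", xlab = "number of features",
       ylab = "cross-validated CHL index", ...)
  graphics::abline(v = length(x$selected), lty = 2)
  invisible(x)
}
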