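#' Confusion-matrix counts
#'
#' Container for the four outcome counts of a binary evaluation: true
#' positives, false negatives, false positives and true negatives.
#'
#' @param tp,fn,fp,tn Non-negative integer counts. `tp + fn` is the number of
#'   true interactions evaluated, `fp + tn` the number of non-interactions.
#' @return An object of class `confusion_counts`, a named integer vector with
#'   elements `tp`, `fn`, `fp`, `tn`.
#' @examples
#' confusion_counts(tp = 2586, fn = 2, fp = 5, tn = 2583)
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  x <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("confusion counts must be non-negative integers")
  structure(as.integer(round(x)), names = names(x), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts: tp=", x["tp"], " fn=", x["fn"],
      " fp=", x["fp"], " tn=", x["tn"], "\n", sep = "")
  invisible(x)
}

#' Full evaluation panel from confusion counts
#'
#' Computes sensitivity, specificity, accuracy, precision, the F1 score,
#' the Matthews correlation coefficient (MCC), its normalization
#' MCC' = (MCC + 1)/2, and the CHL index (see [chl_index()]) from the four
#' outcome counts.
#'
#' Undefined quantities are carried as `NA` and rendered as `"null"` by the
#' report writer: precision and F1 are undefined when no positive call was
#' made (`tp + fp == 0`), and the CHL index is undefined whenever F1 is.
#' MCC with a zero denominator is reported as 0, the convention used for
#' degenerate all-negative or all-positive predictors.
#'
#' @param counts A [confusion_counts()] object (or a numeric vector with
#'   elements `tp`, `fn`, `fp`, `tn`).
#' @return An object of class `metric_panel`: a named list with elements
#'   `sn`, `sp`, `acc`, `precision`, `f1`, `mcc`, `mcc_prime`, `chl`, each a
#'   numeric scalar or `NA` when undefined. The counts are attached as
#'   attribute `"counts"`.
#' @examples
#' panel_from_counts(confusion_counts(2586, 2, 5, 2583))
#' @export
panel_from_counts <- function(counts) {
  if (!inherits(counts, "confusion_counts"))
    counts <- confusion_counts(counts[["tp"]], counts[["fn"]],
                               counts[["fp"]], counts[["tn"]])
  tp <- as.numeric(counts[["tp"]]); fn <- as.numeric(counts[["fn"]])
  fp <- as.numeric(counts[["fp"]]); tn <- as.numeric(counts[["tn"]])
  total <- tp + fn + fp + tn
  if (total == 0) stop("empty evaluation")

  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / total
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (is.na(precision) || is.na(sn)) NA_real_
        else if (precision + sn == 0) NA_real_
        else 2 * precision * sn / (precision + sn)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  mcc_prime <- (mcc + 1) / 2
  chl <- if (is.na(f1)) NA_real_ else chl_index(acc, mcc_prime, f1)

  structure(list(sn = sn, sp = sp, acc = acc, precision = precision,
                 f1 = f1, mcc = mcc, mcc_prime = mcc_prime, chl = chl),
            counts = counts, class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, digits = 4, ...) {
  v <- vapply(x, function(e) format_metric(e, digits), character(1))
  cat(paste0(names(x), "=", v, collapse = "  "), "\n")
  invisible(x)
}

#' @export
as.data.frame.metric_panel <- function(x, row.names = NULL, ...) {
  data.frame(lapply(unclass(x), function(e) if (is.null(e)) NA_real_ else e),
             row.names = row.names)
}

#' The CHL index
#'
#' The CHL index is the harmonic mean of three accuracy measures of a binary
#' classifier — accuracy, the normalized Matthews correlation
#' MCC' = (MCC + 1)/2 and the F1 score:
#' \deqn{CHL = 3 \frac{Acc \cdot MCC' \cdot F_1}{Acc \cdot MCC' + MCC' \cdot F_1 + F_1 \cdot Acc}}
#' It resists the accuracy paradox on imbalanced data while weighting the
#' positive class more heavily than MCC does, and the negative class more
#' heavily than F1 does, which suits interaction prediction where positives
#' are the scientific object of interest.
#'
#' @param acc,mcc_prime,f1 Values in `[0, 1]`. An `NA` input yields `NA`.
#' @return The index in `[0, 1]`; 0 when one input is 0 but a pairwise
#'   product remains positive; `NA` when all pairwise products vanish (the
#'   harmonic mean is then undefined).
#' @examples
#' chl_index(0.7900, 0.5905, 0.8760)
#' @export
chl_index <- function(acc, mcc_prime, f1) {
  v <- c(acc, mcc_prime, f1)
  if (anyNA(v)) return(NA_real_)
  if (any(v < 0 | v > 1)) stop("chl_index inputs must lie in [0, 1]")
  den <- acc * mcc_prime + mcc_prime * f1 + f1 * acc
  if (den == 0) return(NA_real_)
  3 * acc * mcc_prime * f1 / den
}

#' Reconstruct integer counts from printed sensitivity and specificity
#'
#' Inverts rounded Sn/Sp values back to the unique integer confusion counts
#' for known class sizes: `tp` is the integer in `[0, n_pos]` minimizing
#' `|tp/n_pos - sn|` (ties resolved to the larger `tp`), and `tn` analogously.
#' Useful for recomputing full panels from published result tables that print
#' only rates.
#'
#' @param sn,sp Rates in `[0, 1]`.
#' @param n_pos,n_neg Positive class sizes (> 0).
#' @return A [confusion_counts()] object.
#' @examples
#' counts_from_rates(0.9992, 0.9981, 2588, 2588)
#' @export
counts_from_rates <- function(sn, sp, n_pos, n_neg) {
  if (n_pos <= 0 || n_neg <= 0) stop("class sizes must be positive")
  if (any(c(sn, sp) < 0 | c(sn, sp) > 1)) stop("rates must lie in [0, 1]")
  nearest <- function(rate, n) {
    cand <- unique(pmin(n, pmax(0, c(floor(rate * n), ceiling(rate * n)))))
    err <- abs(cand / n - rate)
    best <- cand[err == min(err)]
    max(best)  # tie to the larger count, fixed convention
  }
  tp <- nearest(sn, n_pos)
  tn <- nearest(sp, n_neg)
  confusion_counts(tp = tp, fn = n_pos - tp, fp = n_neg - tn, tn = tn)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.00005 -> 0.0001), the convention
#' used by the published tables this package reproduces; base `round()`
#' rounds ties to even.
#'
#' @param x Numeric.
#' @param digits Number of decimal places (default 4, the table precision).
#' @return Rounded numeric of the same shape.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a metric value for a report cell
#'
#' @param x Scalar metric value or `NA`.
#' @param digits Decimal places.
#' @return `"null"` for undefined values, otherwise a fixed-width decimal
#'   string rounded half-up.
#' @export
format_metric <- function(x, digits = 4) {
  if (is.null(x) || is.na(x)) return("null")
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' Write a metric report table
#'
#' Writes a TSV with one row per evaluated method and columns
#' `method, Sn, Sp, Acc, F1, MCC, MCCprime, CHL`. Undefined cells are
#' emitted as the literal string `"null"`; values are rounded half-up to
#' 4 decimals. An optional comment header records provenance.
#'
#' @param panels Named list of `metric_panel` objects; names become the
#'   `method` column.
#' @param path Output file path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `# `).
#' @return The data.frame written, invisibly.
#' @export
write_metric_report <- function(panels, path, header = NULL) {
  stopifnot(length(panels) > 0, !is.null(names(panels)))
  rows <- lapply(names(panels), function(m) {
    p <- panels[[m]]
    data.frame(method = m,
               Sn = format_metric(p$sn), Sp = format_metric(p$sp),
               Acc = format_metric(p$acc), F1 = format_metric(p$f1),
               MCC = format_metric(p$mcc),
               MCCprime = format_metric(p$mcc_prime),
               CHL = format_metric(p$chl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
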