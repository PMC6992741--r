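# Consistency verification of published benchmark panels: the CHL index
# and MCC' cells of a printed row are redundant — they are recomputable
# from the other printed cells — so arithmetic errors and typos in result
# tables can be detected mechanically.

#' Load the shipped published benchmark panels
#'
#' A fixture of published evaluation rows (Sn, Sp, Acc, F1, MCC, MCC', CHL
#' at 4 printed decimals) for 18 miRNA-target prediction methods under
#' cross-validation and independent testing. `"null"` cells (metrics
#' undefined for degenerate predictors) are read as `NA`.
#'
#' @return Data.frame with columns `set, method, n_pos, n_neg, sn, sp, acc,
#'   f1, mcc, mccprime, chl`.
#' @export
published_panels <- function() {
  path <- system.file("extdata", "published_panels.tsv", package = "mirmeta",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", na.strings = "null",
                    stringsAsFactors = FALSE)
}

#' Verify the internal metric identities of printed panel rows
#'
#' For each row, recomputes `MCC' = (MCC + 1)/2` from the printed MCC and
#' the CHL index from the printed accuracy, MCC' and F1, and compares with
#' the printed cells. Because the printed inputs are themselves rounded to
#' 4 decimals, an exactly recomputed cell can differ from the printed one
#' by up to one unit in the fourth decimal; `tol` (default `1e-4`) is that
#' printed-precision limit. Rows failing at `tol` carry a genuine internal
#' inconsistency (e.g. a typo in one cell).
#'
#' @param panels Data.frame as returned by [published_panels()].
#' @param tol Maximum absolute difference accepted between a printed cell
#'   and its recomputation (default one unit in the last printed place).
#' @return The input with extra columns `mccprime_rc`, `chl_rc` (the
#'   recomputations), `mccprime_ok`, `chl_ok` and `consistent`.
#' @export
verify_panel_identities <- function(panels = published_panels(),
                                    tol = 1e-4) {
  mccprime_rc <- (panels$mcc + 1) / 2
  chl_rc <- mapply(function(a, m, f) {
    if (is.na(f)) NA_real_ else chl_index(a, m, f)
  }, panels$acc, panels$mccprime, panels$f1)
  ok <- function(printed, recomputed) {
    ifelse(is.na(printed) & is.na(recomputed), TRUE,
           abs(printed - recomputed) <= tol + 1e-12)
  }
  panels$mccprime_rc <- mccprime_rc
  panels$chl_rc <- chl_rc
  panels$mccprime_ok <- ok(panels$mccprime, mccprime_rc)
  panels$chl_ok <- ok(panels$chl, chl_rc)
  panels$consistent <- panels$mccprime_ok & panels$chl_ok
  panels
}
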