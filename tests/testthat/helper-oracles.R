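# Independent oracles and small fixtures shared across test files.
# Everything here is written from the defining formulas directly, not by
# calling the package's own implementation, so the two routes can disagree.

# Formula-level metric oracle: straight transliteration of the defining
# ratios, with NaN/Inf mapped to NA.
oracle_panel <- function(tp, fn, fp, tn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sn <- div(tp, tp + fn)
  sp <- div(tn, tn + fp)
  acc <- div(tp + tn, tp + fn + fp + tn)
  prec <- div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sn) || prec + sn == 0) NA_real_
        else 2 * prec * sn / (prec + sn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  mp <- (mcc + 1) / 2
  chl <- if (is.na(f1) || acc * mp + mp * f1 + f1 * acc == 0) NA_real_
         else 3 * acc * mp * f1 / (acc * mp + mp * f1 + f1 * acc)
  list(sn = sn, sp = sp, acc = acc, precision = prec, f1 = f1, mcc = mcc,
       mcc_prime = mp, chl = chl)
}

# Plug-in MI oracle on already-discrete vectors, from the double sum.
oracle_mi <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a)
  mi <- 0
  for (u in unique(a)) for (v in unique(b)) {
    puv <- sum(a == u & b == v) / n
    if (puv > 0)
      mi <- mi + puv * log2(puv / ((sum(a == u) / n) * (sum(b == v) / n)))
  }
  mi
}

# Exhaustive greedy mRMR-MIQ oracle on a small discrete matrix: recompute
# every candidate's quotient at every step from oracle_mi.
oracle_mrmr <- function(xd, y, epsilon = 2^-20) {
  feats <- colnames(xd)
  rel <- sapply(feats, function(f) oracle_mi(xd[, f], y))
  sel <- character(0)
  for (step in seq_along(feats)) {
    rem <- setdiff(feats, sel)
    quot <- sapply(rem, function(f) {
      if (length(sel) == 0) return(rel[[f]])
      red <- mean(sapply(sel, function(s) oracle_mi(xd[, f], xd[, s])))
      rel[[f]] / max(red, epsilon)
    })
    sel <- c(sel, sort(rem[quot == max(quot)])[1])
  }
  sel
}

# Small synthetic study used by several files.
tiny_study <- function(seed = 11, n_mirnas = 12, targets = 6, ...) {
  simulate_study(generator_config(n_mirnas = n_mirnas,
                                  targets_per_mirna = targets,
                                  seed = seed, ...))
}

random_counts <- function(n, seed, max_count = 500) {
  withr::with_seed(seed, replicate(n, {
    repeat {
      x <- sample.int(max_count + 1, 4) - 1L
      if (sum(x) > 0) return(x)
    }
  }))
}
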