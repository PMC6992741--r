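test_that("panel reproduces published cross-validation and perfect rows", {
  # counts reconstructed from the printed Sn/Sp of the energy-extreme CV row
  p <- panel_from_counts(confusion_counts(2586, 2, 5, 2583))
  printed <- c(sn = 0.9992, sp = 0.9981, acc = 0.9986, f1 = 0.9986,
               mcc = 0.9973, chl = 0.9986)
  for (m in names(printed))
    expect_equal(round_half_up(p[[m]]), printed[[m]], tolerance = 0,
                 label = m)
  expect_equal(p$mcc_prime, (p$mcc + 1) / 2)

  perfect <- panel_from_counts(confusion_counts(5, 0, 0, 5))
  for (m in c("sn", "sp", "acc", "precision", "f1", "mcc", "mcc_prime",
              "chl"))
    expect_equal(perfect[[m]], 1, label = m)
})

test_that("all-negative predictor yields MCC 0 and undefined F1/CHL", {
  p <- panel_from_counts(confusion_counts(tp = 0, fn = 10, fp = 0, tn = 10))
  expect_equal(p$sn, 0)
  expect_equal(p$sp, 1)
  expect_equal(p$mcc, 0)          # zero-denominator convention
  expect_true(is.na(p$precision)) # no positive call was made
  expect_true(is.na(p$f1))
  expect_true(is.na(p$chl))
  expect_identical(format_metric(p$f1), "null")
  expect_error(panel_from_counts(confusion_counts(0, 0, 0, 0)),
               "empty evaluation")
})

test_that("chl_index matches published independent-test cells", {
  expect_equal(round_half_up(chl_index(0.7900, 0.5905, 0.8760)), 0.7316)
  # recomputation from 4-decimal inputs can drift one printed ulp
  expect_lt(abs(chl_index(0.4498, 0.5571, 0.5453) - 0.5127), 1e-4)
  expect_equal(chl_index(1, 1, 1), 1)
  expect_true(is.na(chl_index(0, 0, 0)))
  expect_equal(chl_index(0, 0.5, 0.5), 0)
  expect_error(chl_index(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("chl_index is strictly increasing in each argument on (0,1]^3", {
  grid <- withr::with_seed(5, matrix(runif(300, 0.05, 1), ncol = 3))
  for (i in seq_len(nrow(grid))) {
    v <- grid[i, ]
    base <- chl_index(v[1], v[2], v[3])
    for (j in 1:3) {
      up <- v
      up[j] <- min(1, up[j] + 0.04)
      if (up[j] > v[j])
        expect_gt(chl_index(up[1], up[2], up[3]), base)
    }
  }
})

test_that("panel agrees with the formula-level oracle on random matrices", {
  cases <- random_counts(1000, seed = 42)
  for (i in seq_len(ncol(cases))) {
    cc <- cases[, i]
    got <- panel_from_counts(confusion_counts(cc[1], cc[2], cc[3], cc[4]))
    want <- oracle_panel(cc[1], cc[2], cc[3], cc[4])
    for (m in names(want)) {
      if (is.na(want[[m]])) expect_true(is.na(got[[m]]), label = m)
      else expect_equal(got[[m]], want[[m]], tolerance = 1e-12, label = m)
    }
  }
})

test_that("label swap exchanges sn/sp and preserves acc and mcc", {
  cases <- random_counts(100, seed = 7)
  for (i in seq_len(ncol(cases))) {
    cc <- cases[, i]
    a <- panel_from_counts(confusion_counts(cc[1], cc[2], cc[3], cc[4]))
    b <- panel_from_counts(confusion_counts(cc[4], cc[3], cc[2], cc[1]))
    expect_equal(a$acc, b$acc)
    expect_equal(a$mcc, b$mcc, tolerance = 1e-12)
    if (!is.na(a$sn) && !is.na(b$sp)) expect_equal(a$sn, b$sp)
    if (!is.na(a$sp) && !is.na(b$sn)) expect_equal(a$sp, b$sn)
  }
})

test_that("mcc_prime is the affine map of mcc onto [0,1]", {
  cases <- random_counts(200, seed = 3)
  for (i in seq_len(ncol(cases))) {
    cc <- cases[, i]
    p <- panel_from_counts(confusion_counts(cc[1], cc[2], cc[3], cc[4]))
    expect_equal(p$mcc_prime, (p$mcc + 1) / 2)
    expect_true(p$mcc_prime >= 0 && p$mcc_prime <= 1)
  }
  degenerate <- panel_from_counts(confusion_counts(0, 5, 0, 5))
  expect_identical(degenerate$mcc_prime, 0.5)
})

test_that("counts_from_rates matches brute force and round-trips", {
  brute <- function(rate, n) {
    err <- abs((0:n) / n - rate)
    max((0:n)[err == min(err)])
  }
  cases <- withr::with_seed(9, data.frame(sn = runif(50), sp = runif(50),
                                          P = sample(5:400, 50, TRUE),
                                          N = sample(5:400, 50, TRUE)))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    cc <- counts_from_rates(cs$sn, cs$sp, cs$P, cs$N)
    expect_identical(cc[["tp"]], as.integer(brute(cs$sn, cs$P)))
    expect_identical(cc[["tn"]], as.integer(brute(cs$sp, cs$N)))
    p <- panel_from_counts(cc)
    expect_lte(abs(p$sn - cs$sn), 1 / (2 * min(cs$P, cs$N)) + 1e-12)
    expect_lte(abs(p$sp - cs$sp), 1 / (2 * min(cs$P, cs$N)) + 1e-12)
  }
  expect_identical(unclass(counts_from_rates(1, 1, 10, 10)),
                   unclass(confusion_counts(10, 0, 0, 10)))
  # independent-test class sizes: inversion of a printed row
  expect_identical(unclass(counts_from_rates(0.8840, 0.2900, 1248, 241)),
                   unclass(confusion_counts(1103, 145, 171, 70)))
})

test_that("metric report renders undefined cells as null", {
  panels <- list(good = panel_from_counts(confusion_counts(8, 2, 1, 9)),
                 degenerate = panel_from_counts(confusion_counts(0, 9, 0, 9)))
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_metric_report(panels, path, header = "seed=1")
  lines <- readLines(path)
  expect_match(lines[1], "^# seed=1")
  tab <- read.delim(path, comment.char = "#", colClasses = "character")
  expect_identical(names(tab), c("method", "Sn", "Sp", "Acc", "F1", "MCC",
                                 "MCCprime", "CHL"))
  expect_identical(tab$F1[2], "null")
  expect_identical(tab$CHL[2], "null")
  expect_identical(tab$MCC[2], "0.0000")
})

test_that("rounding is half-up at 4 decimals as in printed tables", {
  expect_equal(round_half_up(0.99865), 0.9987)
  expect_equal(round_half_up(0.12344999), 0.1234)
  expect_equal(round_half_up(-0.00005), -0.0001)
})
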