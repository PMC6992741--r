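itable <- function(mirnas, targets_per, seed = 1, labels = TRUE) {
  tab <- expand.grid(mirna_id = sprintf("m%02d", seq_len(mirnas)),
                     target_id = sprintf("g%02d", seq_len(targets_per)),
                     stringsAsFactors = FALSE)
  tab <- tab[order(tab$mirna_id, tab$target_id), ]
  tab$energy <- withr::with_seed(seed, runif(nrow(tab), -30, -5))
  if (labels) tab$label <- withr::with_seed(seed + 1,
    sample(c("positive", "negative"), nrow(tab), TRUE))
  rownames(tab) <- NULL
  tab
}

test_that("per-miRNA energy ranking sorts ascending with lexicographic ties", {
  tab <- data.frame(mirna_id = "m1", target_id = c("g1", "g2", "g3"),
                    energy = c(-25, -10, -18))
  r <- rank_pairs_by_energy(tab)
  expect_identical(r$m1$target_id, c("g1", "g3", "g2"))

  tie <- data.frame(mirna_id = "m1", target_id = c("g_b", "g_a"),
                    energy = c(-20, -20))
  expect_identical(rank_pairs_by_energy(tie)$m1$target_id, c("g_a", "g_b"))

  single <- data.frame(mirna_id = "m1", target_id = "g1", energy = -12)
  expect_equal(nrow(rank_pairs_by_energy(single)$m1), 1)

  bad <- data.frame(mirna_id = "m1", target_id = c("g1", "g2"),
                    energy = c(-12, NA))
  expect_error(rank_pairs_by_energy(bad), "g2")
})

test_that("trA takes each miRNA's energy extremes, brute-force checked", {
  tab <- itable(4, 5, seed = 2, labels = FALSE)
  ts <- build_training_set(tab, "trA")
  expect_equal(nrow(ts$records), 8)
  for (m in unique(tab$mirna_id)) {
    d <- tab[tab$mirna_id == m, ]
    recs <- ts$records[ts$records$mirna_id == m, ]
    expect_identical(recs$target_id[recs$label == "positive"],
                     d$target_id[which.min(d$energy)])
    expect_identical(recs$target_id[recs$label == "negative"],
                     d$target_id[which.max(d$energy)])
  }
  # positive/negative halves are disjoint, one record per miRNA each
  key <- paste(ts$records$mirna_id, ts$records$target_id)
  expect_false(anyDuplicated(key) > 0)
  expect_equal(unname(table(ts$records$label,
                            ts$records$mirna_id)["positive", ]),
               rep(1L, 4))
  # every positive-half energy is below every negative-half energy per miRNA
  for (m in unique(tab$mirna_id)) {
    recs <- ts$records[ts$records$mirna_id == m, ]
    expect_lte(max(recs$energy[recs$label == "positive"]),
               min(recs$energy[recs$label == "negative"]))
  }
})

test_that("trB/trC sizes are 4 per miRNA with deterministic construction", {
  tab <- itable(6, 8, seed = 3, labels = FALSE)
  for (mode in c("trB", "trC")) {
    ts <- build_training_set(tab, mode)
    expect_equal(nrow(ts$records), 24)
    expect_equal(sum(ts$records$label == "positive"), 12)
    key <- paste(ts$records$mirna_id, ts$records$target_id)
    expect_false(anyDuplicated(key) > 0)
    expect_identical(ts$records, build_training_set(tab, mode)$records)
  }
  # trB picks the two most stable and two most unstable per miRNA
  ts <- build_training_set(tab, "trB")
  for (m in unique(tab$mirna_id)) {
    d <- tab[tab$mirna_id == m, ]
    d <- d[order(d$energy), ]
    recs <- ts$records[ts$records$mirna_id == m, ]
    expect_setequal(recs$target_id[recs$label == "positive"],
                    d$target_id[1:2])
    expect_setequal(recs$target_id[recs$label == "negative"],
                    d$target_id[7:8])
  }
  # trC mid-range records sit nearest the per-miRNA median energy
  tc <- build_training_set(tab, "trC")
  for (m in unique(tab$mirna_id)) {
    d <- tab[tab$mirna_id == m, ]
    med <- median(d$energy)
    recs <- tc$records[tc$records$mirna_id == m, ]
    mid <- recs[!(recs$energy %in% c(min(d$energy), max(d$energy))), ]
    free <- d[!(d$energy %in% c(min(d$energy), max(d$energy))), ]
    best2 <- free[order(abs(free$energy - med), free$energy), ][1:2, ]
    expect_setequal(mid$target_id, best2$target_id)
  }
})

test_that("single-candidate miRNAs trigger the cross-miRNA fallback", {
  tab <- rbind(itable(3, 5, seed = 4, labels = FALSE),
               data.frame(mirna_id = "m99", target_id = "g01",
                          energy = -28))
  ts <- build_training_set(tab, "trA")
  expect_equal(nrow(ts$records), 8)  # totals kept at 2 per miRNA
  key <- paste(ts$records$mirna_id, ts$records$target_id)
  expect_false(anyDuplicated(key) > 0)
  # m99's only (very stable) pair lands in the positive half
  m99 <- ts$records[ts$records$mirna_id == "m99", ]
  expect_identical(m99$label, "positive")

  tb <- build_training_set(tab, "trB")
  expect_equal(nrow(tb$records), 16)
  expect_equal(sum(tb$records$label == "positive"), 8)
})

test_that("trR is a seeded uniform sample preserving labels", {
  tab <- itable(5, 10, seed = 5)
  ts1 <- build_training_set(tab, "trR", seed = 42, size = 20)
  ts2 <- build_training_set(tab, "trR", seed = 42, size = 20)
  expect_identical(ts1$records, ts2$records)
  expect_equal(nrow(ts1$records), 20)
  expect_true(all(ts1$records$label %in% c("positive", "negative")))
  expect_error(build_training_set(tab, "trR", seed = 1, size = 99),
               "exceeds")
  expect_error(build_training_set(tab[0, ], "trA"), "empty")
})

test_that("permutation negatives avoid positives and reproduce per seed", {
  pos <- data.frame(mirna_id = c("m1", "m2"), target_id = c("g1", "g2"))
  forced <- generate_negatives_by_permutation(pos, c("g1", "g2"), 1, 2)
  expect_setequal(paste(forced$mirna_id, forced$target_id),
                  c("m1 g2", "m2 g1"))

  pos2 <- itable(6, 6, seed = 6)[, c("mirna_id", "target_id")]
  uni <- sprintf("g%02d", 1:20)
  neg <- generate_negatives_by_permutation(pos2, uni, seed = 9, n = 50)
  expect_equal(nrow(neg), 50)
  expect_length(intersect(paste(neg$mirna_id, neg$target_id),
                          paste(pos2$mirna_id, pos2$target_id)), 0)
  expect_false(anyDuplicated(paste(neg$mirna_id, neg$target_id)) > 0)
  expect_identical(neg,
                   generate_negatives_by_permutation(pos2, uni, 9, 50))
  expect_error(generate_negatives_by_permutation(pos, c("g1", "g2"), 1, 3),
               "insufficient")
})

test_that("P/N ratio enforcement subsamples exactly and errors when absurd", {
  pos <- data.frame(mirna_id = sprintf("m%d", 1:100), target_id = "g")
  neg <- data.frame(mirna_id = sprintf("n%d", 1:300), target_id = "g")
  b1 <- enforce_pn_ratio(pos, neg, ratio = 1, seed = 1)
  expect_equal(c(nrow(b1$pos), nrow(b1$neg)), c(100, 100))
  b2 <- enforce_pn_ratio(pos, neg, ratio = 0.5, seed = 1)
  expect_equal(c(nrow(b2$pos), nrow(b2$neg)), c(100, 200))
  b3 <- enforce_pn_ratio(pos, neg[1:50, , drop = FALSE], ratio = 1,
                         seed = 1)
  expect_equal(c(nrow(b3$pos), nrow(b3$neg)), c(50, 50))
  expect_error(enforce_pn_ratio(pos, neg, ratio = 0), "positive")
})

test_that("stratified folds partition records with per-fold balance", {
  y <- rep(c("positive", "negative"), each = 50)
  f <- stratified_kfold(y, 10, seed = 2)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 10))
  expect_true(all(table(f, y) == 5))
  expect_identical(f, stratified_kfold(y, 10, seed = 2))
  expect_false(identical(f, stratified_kfold(y, 10, seed = 3)))

  # leave-one-out on 10 records is allowed
  f2 <- stratified_kfold(rep(c("positive", "negative"), 5), 10, seed = 1)
  expect_true(all(table(f2) == 1))
  expect_error(stratified_kfold(y, 101, seed = 1), "exceeds")
})

test_that("gene-list subsetting preserves order and handles edge lists", {
  tab <- itable(3, 4, seed = 8)
  expect_identical(subset_by_gene_list(tab, unique(tab$target_id)), tab)
  expect_equal(nrow(subset_by_gene_list(tab, "absent")), 0)
  one <- subset_by_gene_list(tab, "g02")
  expect_true(all(one$target_id == "g02"))
  ts <- build_training_set(tab, "trA")
  sub <- subset_by_gene_list(ts, "g01")
  expect_s3_class(sub, "training_set")
  expect_true(all(sub$records$target_id == "g01"))
})
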