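test_that("seed-type encoding is a fixed 7-dimensional indicator", {
  canon <- canonical_seed_types()
  expect_length(canon, 7)

  none <- encode_seed_types(character(0))
  expect_identical(unname(none), rep(0L, 7))

  one <- encode_seed_types(canon[1])
  expect_identical(unname(one), c(1L, rep(0L, 6)))
  expect_identical(names(one), canon)

  all7 <- encode_seed_types(canon)
  expect_identical(unname(all7), rep(1L, 7))
  expect_length(all7, 7)

  expect_error(encode_seed_types("9mer"), "unknown seed type")
  expect_error(encode_seed_types("9mer"), "8mer") # lists accepted names
})

test_that("nucleotide composition sums to one and handles absent sites", {
  u <- encode_nucleotide_composition("AUGC", c(start = 1, end = 4))
  expect_equal(unname(u), c(0.25, 0.25, 0.25, 0.25, 0.5))

  a <- encode_nucleotide_composition("AAAA", c(start = 1, end = 4))
  expect_equal(unname(a), c(1, 0, 0, 0, 1))

  absent <- encode_nucleotide_composition("AUGC", NULL)
  expect_equal(unname(absent), rep(0, 5))

  # DNA alphabet is mapped to RNA
  t_in <- encode_nucleotide_composition("ACGT", c(start = 1, end = 4))
  expect_equal(t_in[["U"]], 0.25)
  expect_error(encode_nucleotide_composition("ACGN",
                                             c(start = 1, end = 4)),
               "non-ACGU/T")
  expect_error(encode_nucleotide_composition("AUGC",
                                             c(start = 2, end = 9)),
               "past target end")

  sub <- encode_nucleotide_composition("GGGAUAU", c(start = 4, end = 7))
  expect_equal(sub[["AU"]], 1)
  for (i in 1:40) {
    s <- withr::with_seed(i, paste(sample(c("A", "C", "G", "U"), 30,
                                          TRUE), collapse = ""))
    f <- encode_nucleotide_composition(s, c(start = 3, end = 20))
    expect_equal(sum(f[c("A", "C", "G", "U")]), 1)
  }
})

test_that("categorical tool outputs one-hot correctly, zeros when missing", {
  m <- encode_categorical_tool_output("miRanda", "S_C")
  expect_identical(unname(m), c(1L, 0L, 0L, 0L))
  expect_identical(names(m), miranda_categories())

  s <- encode_categorical_tool_output("STarMirDB", "3US")
  expect_identical(sum(s), 1L)
  expect_identical(names(which(s == 1L)), "3US")
  expect_length(s, 6)

  expect_identical(unname(encode_categorical_tool_output("miRanda")),
                   rep(0L, 4))
  expect_error(encode_categorical_tool_output("miRanda", "XX"),
               "unknown miRanda category")
  expect_error(encode_categorical_tool_output("PITA", "S_C"),
               "no categorical encoding")
})

test_that("registry order is fixed, names unique, categories valid", {
  reg <- default_registry()
  expect_false(anyDuplicated(reg$name) > 0)
  expect_true(all(reg$tool %in% supported_tools()))
  expect_setequal(unique(reg$category),
                  c("energy", "scoring function", "evolution evidence",
                    "binding type", "sequence property", "structure"))
  expect_identical(reg$name, default_registry()$name)
  expect_equal(sum(reg$kind == "seed"), 7)
})

test_that("registry round-trips through its YAML configuration", {
  reg <- default_registry()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_identical(back$name, reg$name)
  expect_identical(back$kind, reg$kind)
  expect_identical(back$level, reg$level)
})

test_that("feature vectors are deterministic, order-invariant, missing->0", {
  study <- tiny_study(seed = 21)
  reg <- default_registry()
  pairs <- study$interactions[1:8, ]
  x1 <- assemble_feature_matrix(study$tool_table, pairs,
                                study$sequences$targets, reg)
  # shuffling the tool-table rows never changes the encoding
  shuffled <- study$tool_table[withr::with_seed(
    1, sample.int(nrow(study$tool_table))), ]
  x2 <- assemble_feature_matrix(shuffled, pairs, study$sequences$targets,
                                reg)
  expect_identical(x1, x2)

  # a pair with no records at all encodes as the zero vector
  ghost <- data.frame(mirna_id = "mir_none", target_id = "gene_none")
  z <- assemble_feature_matrix(study$tool_table, ghost, NULL, reg)
  expect_equal(unname(z[1, ]), rep(0, nrow(reg)))

  # records from 2 tools leave all other tools' dimensions at zero
  tt <- study$tool_table
  pair1 <- pairs[1, ]
  sub <- tt[tt$mirna_id == pair1$mirna_id &
              tt$target_id == pair1$target_id &
              tt$tool %in% c("TarPmiR", "RNA22"), ]
  v <- assemble_feature_vector(pair1$mirna_id, pair1$target_id, sub,
                               study$sequences$targets[[pair1$target_id]],
                               reg)
  other <- reg$name[!reg$tool %in% c("TarPmiR", "RNA22")]
  expect_equal(unname(v[other]), rep(0, length(other)))
})

test_that("one-hot groups carry at most one 1 and compositions sum to 0/1", {
  study <- tiny_study(seed = 33)
  reg <- default_registry()
  pairs <- study$interactions[seq(1, nrow(study$interactions), by = 7), ]
  x <- assemble_feature_matrix(study$tool_table, pairs,
                               study$sequences$targets, reg)
  for (grp in list(paste0("miRanda_", miranda_categories()),
                   paste0("STMDB_", starmirdb_categories()))) {
    expect_true(all(rowSums(x[, grp, drop = FALSE]) <= 1))
  }
  comp <- x[, c("TargetScan_comp_A", "TargetScan_comp_C",
                "TargetScan_comp_G", "TargetScan_comp_U"), drop = FALSE]
  sums <- rowSums(comp)
  expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
})

test_that("duplicate tool records error unless aggregation is enabled", {
  rec <- data.frame(
    mirna_id = "m1", target_id = "g1", tool = "RNAhybrid",
    field = rep(c("call", "mfe"), 2),
    value = c("1", "-30", "0", "-10"), stringsAsFactors = FALSE)
  reg <- default_registry()
  expect_error(assemble_feature_vector("m1", "g1", rec, NULL, reg),
               "duplicate records")
  v <- assemble_feature_vector("m1", "g1", rec, NULL, reg,
                               aggregate = "most_stable")
  expect_equal(v[["RNAhybrid_mfe"]], -30)  # kept the most stable record
  expect_equal(v[["RNAhybrid_call"]], 1)

  wrong <- rec
  wrong$mirna_id <- "m2"
  expect_error(assemble_feature_vector("m1", "g1", wrong, NULL, reg),
               "different pair")
})
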