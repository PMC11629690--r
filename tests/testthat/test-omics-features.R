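test_that("omics TSV loader preserves row order and rejects malformed tables", {
  dir <- withr::local_tempdir()
  writeLines(c("gene_id\tc1\tc2", "G1\t1.5\t2", "G2\t0\t-1", "G3\t3\t4"),
             file.path(dir, "ok.tsv"))
  prof <- load_omics_matrix(file.path(dir, "ok.tsv"), "EXP")
  expect_identical(prof$feature_names, c("G1", "G2", "G3"))
  expect_identical(prof$cell_ids, c("c1", "c2"))
  expect_identical(unname(prof$values["G3", "c2"]), 4)

  writeLines(c("gene_id\tc1", "G1\t1", "G1\t2"), file.path(dir, "dup.tsv"))
  expect_error(load_omics_matrix(file.path(dir, "dup.tsv"), "EXP"), "duplicate gene ids.*G1")

  writeLines(c("gene_id\tc1\tc2", "G1\t1\tx", "G2\t2\t3"), file.path(dir, "bad.tsv"))
  expect_error(load_omics_matrix(file.path(dir, "bad.tsv"), "EXP"), "row 1.*G1.*c2")

  fx <- cached_fixture()$fx
  d2 <- withr::local_tempdir()
  write_fixture(fx, d2)
  exp2 <- load_omics_matrix(file.path(d2, "exp.tsv"), "EXP")
  expect_identical(dim(exp2$values), c(50L, 20L))
  expect_true(all(is.finite(exp2$values)))
  expect_equal(exp2$values, fx$exp$values)
})

test_that("pathway scores are mean within-cell z-scores and order-invariant", {
  set.seed(21)
  vals <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("G", 1:10), c("c1", "c2")))
  exp <- cell_profiles(vals, "EXP")
  sets <- list(all = paste0("G", 1:10), one = "G3", five = paste0("G", c(1, 4, 5, 8, 9)))

  pes <- compute_pathway_scores(exp, sets)
  # full-profile set: mean of a complete z-scored vector is 0
  expect_equal(unname(pes$values["all", ]), c(0, 0), tolerance = 1e-12)
  # 1-gene set: that gene's z-score
  z <- (vals["G3", "c1"] - mean(vals[, "c1"])) / sd(vals[, "c1"])
  expect_equal(unname(pes$values["one", "c1"]), z, tolerance = 1e-12)
  # 5-gene set: brute-force mean-of-z oracle
  zs <- (vals[, "c2"] - mean(vals[, "c2"])) / sd(vals[, "c2"])
  expect_equal(unname(pes$values["five", "c2"]),
               mean(zs[c("G1", "G4", "G5", "G8", "G9")]), tolerance = 1e-12)

  # permuting gene order leaves scores unchanged
  perm <- sample(10)
  pes2 <- compute_pathway_scores(cell_profiles(vals[perm, ], "EXP"), sets)
  expect_equal(pes2$values, pes$values, tolerance = 1e-12)

  expect_warning(compute_pathway_scores(exp, c(sets, list(alien = c("X1", "X2")))),
                 "no overlapping genes")
  expect_error(compute_pathway_scores(exp, list(alien = c("X1", "X2"))), "no gene set overlaps")
})

test_that("GMT gene sets are read as a named collection", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("set1\tdesc\tG1\tG2\tG3", "set2\tdesc\tG2\tG5"), path)
  gs <- read_gene_sets(path)
  expect_named(gs, c("set1", "set2"))
  expect_identical(gs$set2, c("G2", "G5"))
})

test_that("mutation encoding maps truthy strings and rejects other values", {
  m <- matrix(c("TRUE", "FALSE", "false", "true"), 2, 2,
              dimnames = list(c("G1", "G2"), c("c1", "c2")))
  expect_message(prof <- encode_mutation(m), "mapped truthy")
  expect_identical(unname(prof$values), matrix(c(1, 0, 0, 1), 2))
  zero <- matrix(0, 2, 2, dimnames = dimnames(m))
  expect_true(all(encode_mutation(zero)$values == 0))
  bad <- matrix(c("1", "maybe", "0", "1"), 2, 2, dimnames = dimnames(m))
  expect_error(encode_mutation(bad), "maybe")
  expect_error(encode_mutation(matrix(c(0, 2, 1, 0), 2, dimnames = dimnames(m))), "non-binary")
})

test_that("planted mutation rate is recovered within binomial 3 SE", {
  fx <- cached_fixture()$fx
  p <- fx$truth$mut_rate
  n <- length(fx$mut$values)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(fx$mut$values) - p), 3 * se)
})

test_that("CNV encoding is a finite passthrough with optional discretisation", {
  toy <- matrix(c(0.3, -1.2, 0, 2.5), 2, 2,
                dimnames = list(c("G1", "G2"), c("c1", "c2")))
  expect_identical(encode_cnv(toy)$values, toy)
  expect_true(all(encode_cnv(toy * 0)$values == 0))
  expect_error(encode_cnv(matrix(c(1, NA), 1, 2, dimnames = list("G1", c("a", "b")))), "non-finite")
  disc <- encode_cnv(toy, discretize_at = 1)$values
  expect_identical(unname(disc), matrix(c(0, -1, 0, 1), 2))
  # round trip through the fixture writer and loader
  fx <- cached_fixture()$fx
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  reloaded <- load_omics_matrix(file.path(dir, "cnv.tsv"), "CNV")
  expect_equal(encode_cnv(reloaded$values)$values, fx$cnv$values)
})

test_that("gene subset selection follows subset order and is idempotent", {
  fx <- cached_fixture()$fx
  subset <- c("G005", "G001", "G010")
  sel <- select_gene_subset(fx$exp, subset)
  expect_identical(sel$feature_names, subset)
  expect_identical(select_gene_subset(fx$exp, fx$exp$feature_names)$values, fx$exp$values)
  one <- select_gene_subset(fx$exp, "G002")
  expect_identical(nrow(one$values), 1L)
  expect_message(two <- select_gene_subset(fx$exp, c("G001", "NOPE", "G002")), "1 subset gene")
  expect_identical(two$feature_names, c("G001", "G002"))
  expect_identical(select_gene_subset(sel, subset)$values, sel$values)
  expect_error(select_gene_subset(fx$exp, c("X", "Y")), "no overlap")
})

test_that("normalisation statistics fit on training cells are reused without refitting", {
  fx <- cached_fixture()$fx
  train_cells <- fx$exp$cell_ids[1:12]
  test_cells <- fx$exp$cell_ids[13:20]
  norm <- fit_normalizer(cell_profiles(fx$exp$values[, train_cells], "EXP"))
  expect_equal(unname(norm$mean), unname(rowMeans(fx$exp$values[, train_cells])))
  out <- apply_normalizer(norm, cell_profiles(fx$exp$values[, test_cells], "CNV"))
  # stored statistics differ from those the test cells would produce:
  # applying them must use the stored values, not refit
  refit <- fit_normalizer(cell_profiles(fx$exp$values[, test_cells], "EXP"))
  expect_false(isTRUE(all.equal(norm$mean, refit$mean)))
  expect_equal(out$values, (fx$exp$values[, test_cells] - norm$mean) / norm$sd)
  # MUT profiles pass through unscaled
  mnorm <- fit_normalizer(cell_profiles(fx$mut$values[, train_cells], "MUT"))
  expect_identical(apply_normalizer(mnorm, fx$mut)$values, fx$mut$values)
})
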