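toy_records <- function() {
  fc <- cached_fixture()
  fc$fx$responses
}

test_that("strategy and metric registries are complete", {
  expect_identical(length(split_strategies()), 4L)
  expect_setequal(split_strategies(), c("random", "leave_cell_out", "leave_drug_out", "strict"))
  expect_identical(length(response_metrics()), 3L)
  expect_identical(length(metric_names()), 3L)
})

test_that("dataset construction joins responses, profiles and parsable drugs", {
  fc <- cached_fixture()
  dd <- suppressMessages(build_drdata(fc$fx$responses, fc$omics))
  expect_s3_class(dd, "dr_data")
  expect_identical(nrow(dd$records), 160L)  # full 20 x 8 grid

  toy <- fc$fx$responses[1:10, ]
  dd10 <- suppressMessages(build_drdata(toy, fc$omics))
  expect_identical(nrow(dd10$records), 10L)

  unk <- toy
  unk$cell_id[1] <- "NOT_A_CELL"
  expect_message(dd9 <- build_drdata(unk, fc$omics), "no cell profile")
  expect_identical(nrow(dd9$records), 9L)

  expect_error(build_drdata(toy[, c("cell_id", "drug_id")], fc$omics), "missing required")
  expect_error(build_drdata(toy[, c("cell_id", "response")], fc$omics), "drug identifier")
})

test_that("cleaning drops bad responses/SMILES and averages duplicate pairs", {
  dup <- data.frame(
    cell_id = c("c1", "c1"), drug_id = c("d1", "d1"), smiles = "CCO",
    response = c(1, 3), metric = "lnIC50", stringsAsFactors = FALSE
  )
  out <- suppressMessages(clean(dup))
  expect_identical(nrow(out), 1L)
  expect_identical(out$response, 2)

  nan_rec <- data.frame(cell_id = "c2", drug_id = "d1", smiles = "CCO",
                        response = NaN, metric = "lnIC50")
  expect_identical(nrow(suppressMessages(clean(rbind(dup, nan_rec)))), 1L)

  # 12-row toy: 2 records with bad SMILES + 1 duplicated pair -> 9 survive
  toy12 <- data.frame(
    cell_id = c("c1", "c1", "c2", "c2", "c3", "c3", "c4", "c4", "c5", "c5", "c1", "c2"),
    drug_id = c("d1", "d2", "d1", "d2", "d1", "d2", "d1", "d2", "d1", "dX", "d1", "dY"),
    smiles = c("CCO", "c1ccccc1", "CCO", "c1ccccc1", "CCO", "c1ccccc1",
               "CCO", "c1ccccc1", "CCO", "not_a_smiles", "CCO", "((("),
    response = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
    metric = "lnIC50", stringsAsFactors = FALSE
  )
  out12 <- suppressMessages(clean(toy12))
  expect_identical(nrow(out12), 9L)
  expect_identical(out12$response[out12$cell_id == "c1" & out12$drug_id == "d1"], 6)  # mean(1, 11)
  expect_error(suppressMessages(clean(toy12[10, ])), "no records remain")
})

test_that("random split follows the floor-then-remainder-to-train rule", {
  recs <- data.frame(
    cell_id = rep(sprintf("c%02d", 1:50), each = 20),
    drug_id = rep(sprintf("d%02d", 1:20), times = 50),
    smiles = "CCO", response = rnorm(1000), metric = "lnIC50",
    stringsAsFactors = FALSE
  )
  sp <- split_records(recs, "random", c(0.8, 0.1, 0.1), seed = 1L)
  expect_identical(c(nrow(sp$train), nrow(sp$val), nrow(sp$test)), c(800L, 100L, 100L))
  # remainder goes to train
  sp7 <- split_records(recs[1:107, ], "random", c(0.8, 0.1, 0.1), seed = 1L)
  expect_identical(c(nrow(sp7$train), nrow(sp7$val), nrow(sp7$test)), c(87L, 10L, 10L))
})

test_that("splits are pure functions of (records, strategy, fractions, seed)", {
  recs <- toy_records()
  for (strategy in split_strategies()) {
    a <- split_records(recs, strategy, seed = 3L)
    b <- split_records(recs, strategy, seed = 3L)
    expect_identical(a$train, b$train)
    expect_identical(a$test, b$test)
    c2 <- split_records(recs, strategy, seed = 4L)
    expect_false(identical(a$train, c2$train))
  }
})

test_that("entity-disjointness and record conservation hold across seeds 1-10", {
  recs <- toy_records()
  for (seed in 1:10) {
    for (strategy in split_strategies()) {
      sp <- split_records(recs, strategy, seed = seed)
      # record-level disjointness for every strategy
      key <- function(d) paste(d$cell_id, d$drug_id)
      expect_length(intersect(key(sp$train), key(sp$val)), 0L)
      expect_length(intersect(key(sp$train), key(sp$test)), 0L)
      expect_length(intersect(key(sp$val), key(sp$test)), 0L)
      if (strategy == "leave_cell_out") {
        expect_length(intersect(sp$train$cell_id, sp$test$cell_id), 0L)
        expect_length(intersect(sp$train$cell_id, sp$val$cell_id), 0L)
        expect_length(intersect(sp$val$cell_id, sp$test$cell_id), 0L)
        expect_identical(nrow(sp$train) + nrow(sp$val) + nrow(sp$test), nrow(recs))
      }
      if (strategy == "leave_drug_out") {
        expect_length(intersect(sp$train$drug_id, sp$test$drug_id), 0L)
        expect_identical(nrow(sp$train) + nrow(sp$val) + nrow(sp$test), nrow(recs))
      }
      if (strategy == "strict") {
        expect_length(intersect(sp$train$cell_id, sp$test$cell_id), 0L)
        expect_length(intersect(sp$train$drug_id, sp$test$drug_id), 0L)
        expect_identical(nrow(sp$train) + nrow(sp$val) + nrow(sp$test) + nrow(sp$discarded),
                         nrow(recs))
      }
    }
  }
})

test_that("splitting refuses inputs with too few entities", {
  recs <- toy_records()
  few <- recs[recs$cell_id %in% unique(recs$cell_id)[1:4], ]
  expect_error(split_records(few, "leave_cell_out", c(0.5, 0.25, 0.25), seed = 1L), NA)
  expect_error(split_records(few[few$drug_id == "ethanol", ], "leave_drug_out", seed = 1L),
               "too few entities.*at least")
})

test_that("split serialisation writes three CSVs plus a manifest", {
  dir <- withr::local_tempdir()
  sp <- suppressMessages(split_records(toy_records(), "strict", seed = 2L))
  write_split(sp, dir)
  expect_true(all(file.exists(file.path(dir, c("train.csv", "val.csv", "test.csv", "manifest.json")))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(man$strategy, "strict")
  expect_identical(man$sizes$train, nrow(sp$train))
})

test_that("loaders cover every record once per epoch, reproducibly", {
  ld <- make_loader(10L, batch_size = 3L, shuffle = FALSE)
  b <- ld$batches(1L)
  expect_identical(lengths(b), c(`1` = 3L, `2` = 3L, `3` = 3L, `4` = 1L))
  expect_identical(sort(unname(unlist(b))), 1:10)
  expect_identical(ld$batches(1L), ld$batches(2L))  # shuffle off: same order

  ls1 <- make_loader(50L, batch_size = 8L, shuffle = TRUE, seed = 9L)
  ls2 <- make_loader(50L, batch_size = 8L, shuffle = TRUE, seed = 9L)
  expect_identical(ls1$batches(1L), ls2$batches(1L))
  expect_identical(ls1$batches(3L), ls2$batches(3L))
  expect_false(identical(ls1$batches(1L), ls1$batches(2L)))
  expect_identical(sort(unname(unlist(ls1$batches(2L)))), 1:50)
})

test_that("public-dataset loader gives instructive errors and parses placed files", {
  dir <- withr::local_tempdir()
  expect_error(load_public_dataset("CCLE", dir), "Expected layout")
  expect_error(load_public_dataset("TCGA", dir), "arg")
  fx <- cached_fixture()$fx
  write_fixture(fx, file.path(dir, "CCLE"))
  dd <- suppressMessages(load_public_dataset("CCLE", dir))
  expect_s3_class(dd, "dr_data")
  expect_identical(nrow(dd$records), 160L)
})
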