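test_that("metrics agree with brute-force formulas on random vectors", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    truth <- rnorm(n, sd = runif(1, 0.5, 3))
    pred <- truth + rnorm(n, sd = runif(1, 0, 2))
    rep <- eval_metrics(pred, truth)
    # independent elementwise formulas
    mse_bf <- sum((pred - truth)^2) / n
    r2_bf <- 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
    mu_p <- sum(pred) / n; mu_t <- sum(truth) / n
    pcc_bf <- sum((pred - mu_p) * (truth - mu_t)) /
      sqrt(sum((pred - mu_p)^2) * sum((truth - mu_t)^2))
    expect_equal(rep$mse, mse_bf, tolerance = 1e-10)
    expect_equal(rep$r2, r2_bf, tolerance = 1e-10)
    expect_equal(rep$pcc, pcc_bf, tolerance = 1e-10)
    expect_lte(rep$r2, 1)
    expect_true(rep$pcc >= -1 && rep$pcc <= 1)
    expect_gte(rep$mse, 0)
  }
})

test_that("metric boundary cases are exact", {
  truth <- c(1, 2, 3, 4)
  perfect <- eval_metrics(truth, truth)
  expect_identical(perfect$mse, 0)
  expect_identical(perfect$r2, 1)
  expect_identical(perfect$pcc, 1)
  # predicting the mean: R^2 is exactly 0 (PCC undefined for constant pred)
  at_mean <- eval_metrics(rep(mean(truth), 4), truth)
  expect_identical(at_mean$r2, 0)
  expect_true(at_mean$pcc_undefined)
  expect_true(is.na(at_mean$pcc))
  # hand-computed example
  rep <- eval_metrics(c(3, 2, 1), c(1, 2, 3))
  expect_equal(rep$pcc, -1)
  expect_equal(rep$mse, 8 / 3)
  # zero-variance truth: flagged, not silently NaN
  zv <- eval_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_true(zv$pcc_undefined)
  expect_true(is.na(zv$pcc))
})

make_training_setup <- function(n_records = 24L, seed = 2L) {
  fc <- cached_fixture()
  hp <- small_hp()
  mc <- model_config("FP_DNN", "DNN_EXP", "DNN_FUSION", hp, seed = seed)
  recs <- fc$fx$responses[seq_len(n_records), ]
  tr <- dr_dataset(recs, fc$omics, mc)
  va <- dr_dataset(fc$fx$responses[(n_records + 1):(n_records + 8), ], fc$omics, mc,
                   state = tr$state)
  list(mc = mc, tr = tr, va = va, hp = hp)
}

test_that("training is seeded, records history, and tracks the best epoch", {
  s <- make_training_setup()
  m1 <- build_model(s$mc, s$tr)
  r1 <- train_model(m1, s$tr, s$va, epochs = 5L, learning_rate = 1e-3, seed = 7L)
  expect_identical(nrow(r1$history), 5L)
  expect_identical(r1$best_epoch, which.min(r1$history$val_mse))
  m2 <- build_model(s$mc, s$tr)
  r2 <- train_model(m2, s$tr, s$va, epochs = 5L, learning_rate = 1e-3, seed = 7L)
  expect_identical(r1$history, r2$history)  # bitwise-identical loss history
  m3 <- build_model(s$mc, s$tr)
  r3 <- train_model(m3, s$tr, s$va, epochs = 1L, learning_rate = 1e-3, seed = 7L)
  expect_identical(nrow(r3$history), 1L)
})

test_that("a small model overfits ten records to near-zero training error", {
  fc <- cached_fixture()
  hp <- small_hp()
  mc <- model_config("FP_DNN", "DNN_EXP", "DNN_FUSION", hp, seed = 2L)
  recs <- fc$fx$responses[seq(1, 160, by = 16), ]
  ds <- dr_dataset(recs, fc$omics, mc)
  m <- build_model(mc, ds)
  run <- train_model(m, ds, ds, epochs = 500L, learning_rate = 3e-3, seed = 2L,
                     batch_size = 10L, stop_at_train_mse = 1e-3)
  expect_lt(min(run$history$train_mse), 1e-2)
})

test_that("evaluate and predict agree, and checkpoints round-trip bitwise", {
  s <- make_training_setup()
  m <- build_model(s$mc, s$tr)
  run <- train_model(m, s$tr, s$va, epochs = 3L, learning_rate = 1e-3, seed = 1L)
  m <- restore_best(run)
  rep <- evaluate_model(m, s$va)
  expect_s3_class(rep, "eval_report")
  expect_identical(rep$n, nrow(s$va$records))

  ckpt <- withr::local_tempfile(fileext = ".ckpt")
  write_checkpoint(m, s$tr, ckpt)
  in_mem <- model_predict(m, s$va)
  pairs <- data.frame(cell_id = s$va$records$cell_id, smiles = s$va$records$smiles)
  out <- predict_response(ckpt, pairs)
  expect_identical(out$prediction, unname(in_mem))  # bitwise reproduction
  expect_true(all(is.na(out$error)))

  # training pair: predict equals evaluate-time prediction
  tr_pairs <- data.frame(cell_id = s$tr$records$cell_id[1], smiles = s$tr$records$smiles[1])
  expect_identical(predict_response(ckpt, tr_pairs)$prediction,
                   unname(model_predict(m, s$tr, 1L)))

  # per-pair errors, not batch failure
  mixed <- data.frame(cell_id = c(s$va$records$cell_id[1], "NOT_A_CELL"),
                      smiles = c(s$va$records$smiles[1], "CCO"))
  res <- predict_response(ckpt, mixed)
  expect_true(is.na(res$prediction[2]))
  expect_match(res$error[2], "unknown cell_id")
  expect_false(is.na(res$prediction[1]))

  # empty input gives an empty frame
  expect_identical(nrow(predict_response(ckpt, data.frame(cell_id = character(0),
                                                          smiles = character(0)))), 0L)
})

test_that("training aborts with diagnostics on divergence", {
  s <- make_training_setup()
  m <- build_model(s$mc, s$tr)
  expect_error(train_model(m, s$tr, s$va, epochs = 30L, learning_rate = 1e150, seed = 1L),
               "diverged")
})

test_that("the benchmark suite defines sixteen named configurations", {
  suite <- benchmark_suite()
  expect_length(suite, 16L)
  expect_identical(anyDuplicated(names(suite)), 0L)
  for (cfg in suite) expect_s3_class(cfg, "model_config")
  # the three literature-style entries use the expected feature pairings
  expect_identical(suite$tCNNS_like$drug_encoder, "SMILES_CNN")
  expect_identical(suite$Precily_like$cell_encoder, "DNN_PES")
  expect_identical(suite$DeepDSC_like$cell_encoder, "DAE_EXP")
})

test_that("the benchmark harness aggregates across seeds and survives failures", {
  fc <- cached_fixture()
  dd <- suppressMessages(build_drdata(fc$fx$responses, fc$omics))
  hp <- small_hp()
  suite <- list(fp_exp = model_config("FP_DNN", "DNN_EXP", "DNN_FUSION", hp))
  res <- suppressMessages(
    run_benchmark(suite, dd, strategies = "random", seeds = c(1L, 2L),
                  lr_grid = 1e-3, epochs = 2L, batch_size = 32L)
  )
  expect_identical(nrow(res), 1L)
  expect_identical(res$seed_count, 2L)
  expect_identical(res$status, "ok")
  expect_true(is.finite(res$mse_sd))

  # identical seeds: deterministic runs make the reported SD exactly 0
  res_same <- suppressMessages(
    run_benchmark(suite, dd, strategies = "random", seeds = c(3L, 3L),
                  lr_grid = 1e-3, epochs = 2L, batch_size = 32L)
  )
  expect_identical(res_same$mse_sd, 0)
  expect_identical(res_same$pcc_sd, 0)

  # a config that cannot be featurized yields a failed row, not an abort
  dd_noexp <- dd
  dd_noexp$omics <- dd$omics["MUT"]
  res2 <- suppressMessages(
    run_benchmark(suite, dd_noexp, strategies = "random", seeds = 1L,
                  lr_grid = 1e-3, epochs = 1L)
  )
  expect_match(res2$status, "failed")
})
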