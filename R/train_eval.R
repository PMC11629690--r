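# Training loop (MSE objective, Adam), the three evaluation metrics
# (MSE, R-squared, Pearson correlation), checkpoint-based inference, and
# the benchmark harness.

#' Names of the supported evaluation metrics
#' @return Character vector of length 3.
#' @export
metric_names <- function() c("mse", "r2", "pcc")

#' Evaluate predictions against observed responses
#'
#' MSE is the mean squared residual, R-squared is `1 - SS_res / SS_tot`, and
#' PCC is the Pearson correlation of predictions and truth. A zero-variance
#' truth vector makes PCC undefined; it is reported as NA with an explicit
#' `pcc_undefined` flag rather than silently.
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return An object of class `eval_report`: `mse`, `r2`, `pcc`, `n`,
#'   `pcc_undefined`.
#' @export
eval_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1L)
  mse <- mean((pred - truth)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum((truth - pred)^2) / ss_tot
  pcc_undefined <- stats::sd(truth) == 0 || stats::sd(pred) == 0
  pcc <- if (pcc_undefined) NA_real_ else stats::cor(pred, truth)
  structure(list(mse = mse, r2 = r2, pcc = pcc, n = length(pred),
                 pcc_undefined = pcc_undefined),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  MSE=%.4f  R2=%s  PCC=%s%s\n", x$n, x$mse,
              formatC(x$r2, format = "f", digits = 4),
              formatC(x$pcc, format = "f", digits = 4),
              if (x$pcc_undefined) "  [PCC undefined: zero-variance input]" else ""))
  invisible(x)
}

#' Train a drug-response model
#'
#' Minimises MSE with Adam; validation MSE is computed every epoch and the
#' returned checkpoint weights come from the best-validation epoch. Fully
#' seeded: the same seed reproduces the loss history exactly.
#'
#' @param model A [build_model()] result (modified in place and returned).
#' @param train_set,val_set Featurized `dr_dataset`s sharing one state.
#' @param epochs Number of epochs (>= 1).
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed covering batch shuffling.
#' @param batch_size Records per gradient step.
#' @param weight_decay Decoupled weight-decay coefficient (default 0);
#'   useful when few training cells make the cell branch prone to
#'   memorisation.
#' @param stop_at_train_mse Optional threshold: training halts early once the
#'   epoch-mean training MSE falls below it (history is truncated to the
#'   completed epochs).
#' @param verbose Print per-epoch losses.
#' @return An object of class `train_run`: the trained `model`, `history`
#'   (data frame epoch/train_mse/val_mse), `best_epoch`, `best_params`
#'   (weights at the best-validation epoch).
#' @export
train_model <- function(model, train_set, val_set, epochs = 100L,
                        learning_rate = 1e-3, seed = 1L, batch_size = 32L,
                        weight_decay = 0, stop_at_train_mse = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "dr_model"), epochs >= 1L,
            nrow(train_set$records) > 0L, nrow(val_set$records) > 0L)
  loader <- make_loader(nrow(train_set$records), batch_size = batch_size,
                        shuffle = TRUE, seed = seed)
  set.seed(seed)
  history <- data.frame(epoch = seq_len(epochs), train_mse = NA_real_, val_mse = NA_real_)
  best <- list(val = Inf, epoch = NA_integer_, values = NULL)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ep_losses <- c()
    for (b in loader$batches(ep)) {
      ad_begin()
      fw <- tryCatch(model_forward(model, train_set, b), error = function(e) {
        if (grepl("non-finite", conditionMessage(e))) {
          stop("training diverged at epoch ", ep, " (", conditionMessage(e), "); ",
               "try a smaller learning rate (current ", learning_rate, ")", call. = FALSE)
        }
        stop(e)
      })
      loss <- ad_mse_loss(fw$pred, matrix(fw$targets, ncol = 1L))
      if (!is.finite(loss$val[1L])) {
        stop("training diverged at epoch ", ep, " (non-finite loss); ",
             "try a smaller learning rate (current ", learning_rate, ")")
      }
      ad_zero_grad(model$params)
      ad_backward(loss)
      step <- step + 1L
      adam_step(model$params, learning_rate, step, weight_decay = weight_decay)
      ep_losses <- c(ep_losses, loss$val[1L])
    }
    history$train_mse[ep] <- mean(ep_losses)
    val_pred <- tryCatch(model_predict(model, val_set), error = function(e) {
      if (grepl("non-finite", conditionMessage(e))) {
        stop("training diverged at epoch ", ep, " (", conditionMessage(e), "); ",
             "try a smaller learning rate (current ", learning_rate, ")", call. = FALSE)
      }
      stop(e)
    })
    history$val_mse[ep] <- mean((val_pred - val_set$records$response)^2)
    if (history$val_mse[ep] < best$val) {
      best <- list(val = history$val_mse[ep], epoch = ep,
                   values = ad_param_values(model$params))
    }
    if (verbose) {
      message(sprintf("epoch %3d  train MSE %.5f  val MSE %.5f", ep,
                      history$train_mse[ep], history$val_mse[ep]))
    }
    if (!is.null(stop_at_train_mse) && history$train_mse[ep] < stop_at_train_mse) {
      history <- history[seq_len(ep), , drop = FALSE]
      break
    }
  }
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 best_val_mse = best$val, best_params = best$values,
                 learning_rate = learning_rate, seed = seed),
            class = "train_run")
}

#' Restore a model's weights to the best-validation epoch of a run
#' @param run A `train_run`.
#' @return The run's model with best-epoch weights loaded.
#' @export
restore_best <- function(run) {
  ad_param_load(run$model$params, run$best_params)
  run$model
}

#' Evaluate a model on a featurized dataset
#'
#' @param model A `dr_model`.
#' @param dataset A `dr_dataset` featurized with the model's training state.
#' @return An `eval_report`.
#' @export
evaluate_model <- function(model, dataset) {
  pred <- model_predict(model, dataset)
  eval_metrics(pred, dataset$records$response)
}

#' Predict responses for (cell, drug) pairs from a checkpoint
#'
#' Featurization (vocabulary, gene order, normalisation) is taken from the
#' checkpoint, so predictions are deterministic given the checkpoint file.
#' Pairs whose cell has no stored or supplied profile get a per-pair error
#' entry instead of failing the whole batch.
#'
#' @param checkpoint Path to a [write_checkpoint()] file, or its
#'   [read_checkpoint()] result.
#' @param pairs Data frame with columns `cell_id` and `smiles`.
#' @param omics Optional named list of `cell_profiles` supplying profiles
#'   for cells not seen at training time.
#' @return Data frame `cell_id, smiles, prediction, error`.
#' @export
predict_response <- function(checkpoint, pairs, omics = NULL) {
  ck <- if (is.character(checkpoint)) read_checkpoint(checkpoint) else checkpoint
  if (nrow(pairs) == 0L) {
    return(data.frame(cell_id = character(0), smiles = character(0),
                      prediction = numeric(0), error = character(0)))
  }
  stopifnot(all(c("cell_id", "smiles") %in% names(pairs)))
  cmat <- ck$cell_matrix
  if (!is.null(omics)) {
    cmod <- ck$state$cell_modality
    if (cmod %in% names(omics)) {
      prof <- omics[[cmod]]
      extra <- setdiff(prof$cell_ids, rownames(cmat))
      if (length(extra) > 0L) {
        normed <- apply_normalizer(ck$state$normalizer,
                                   cell_profiles(prof$values[, extra, drop = FALSE], prof$modality))
        cmat <- rbind(cmat, t(normed$values))
      }
    }
  }
  out <- data.frame(cell_id = pairs$cell_id, smiles = pairs$smiles,
                    prediction = NA_real_, error = NA_character_,
                    stringsAsFactors = FALSE)
  known <- pairs$cell_id %in% rownames(cmat)
  out$error[!known] <- "unknown cell_id: no profile available"
  parsable <- vapply(pairs$smiles, function(s) !is.na(s) && is_valid_smiles(s), TRUE)
  out$error[known & !parsable] <- "unparsable SMILES"
  ok <- which(known & parsable)
  if (length(ok) > 0L) {
    recs <- data.frame(cell_id = pairs$cell_id[ok], drug_id = pairs$smiles[ok],
                       smiles = pairs$smiles[ok], response = 0, metric = "lnIC50",
                       stringsAsFactors = FALSE)
    ds <- .dataset_from_state(recs, cmat, ck$state, ck$model$config)
    out$prediction[ok] <- model_predict(ck$model, ds)
  }
  out
}

# Assemble a dr_dataset directly from checkpoint state (already-normalised
# cell matrix), bypassing refitting.
.dataset_from_state <- function(records, cell_matrix, state, config) {
  uniq <- unique(records[, c("drug_id", "smiles")])
  drug_features <- lapply(uniq$smiles, function(s) {
    switch(state$drug_modality,
      FP = compute_fingerprint(s, L = state$fp_length, radius = state$fp_radius),
      SMILES = tokenize_smiles(s, state$vocab, max_len = state$max_len),
      GRAPH = smiles_to_graph(s))
  })
  names(drug_features) <- uniq$drug_id
  structure(list(records = records, drug_features = drug_features,
                 cell_matrix = cell_matrix[unique(records$cell_id), , drop = FALSE],
                 state = state, config = config),
            class = "dr_dataset")
}

# ---- benchmark harness -----------------------------------------------------

#' The 16-configuration benchmark suite
#'
#' Three literature-style configurations — a SMILES-convolution model over
#' mutation profiles (tCNNS-like), a fingerprint model over pathway scores
#' (Precily-like), and a fingerprint model over an expression autoencoder
#' (DeepDSC-like) — plus thirteen further configurations drawn from the
#' model factory to cover every encoder family and both fusion modules.
#'
#' @param hyperparams Shared hyperparameters.
#' @return Named list of 16 `model_config` objects.
#' @export
benchmark_suite <- function(hyperparams = default_hyperparams()) {
  mk <- function(de, ce, fu) model_config(de, ce, fu, hyperparams)
  configs <- list(
    tCNNS_like = mk("SMILES_CNN", "CNN_MUT", "DNN_FUSION"),
    Precily_like = mk("FP_DNN", "DNN_PES", "DNN_FUSION"),
    DeepDSC_like = mk("FP_DNN", "DAE_EXP", "DNN_FUSION"),
    fp_dnn_exp = mk("FP_DNN", "DNN_EXP", "DNN_FUSION"),
    fp_dnn_cnv = mk("FP_DNN", "DNN_CNV", "DNN_FUSION"),
    smiles_gru_exp = mk("SMILES_GRU", "DNN_EXP", "DNN_FUSION"),
    smiles_lstm_exp = mk("SMILES_LSTM", "DNN_EXP", "DNN_FUSION"),
    smiles_gru_exp_mha = mk("SMILES_GRU", "DNN_EXP", "MHA_FUSION"),
    gcn_exp = mk("GRAPH_GCN", "DNN_EXP", "DNN_FUSION"),
    gcn_exp_mha = mk("GRAPH_GCN", "DNN_EXP", "MHA_FUSION"),
    gat_exp = mk("GRAPH_GAT", "DNN_EXP", "DNN_FUSION"),
    mpg_exp = mk("GRAPH_MPG", "DNN_EXP", "DNN_FUSION"),
    attentivefp_exp = mk("GRAPH_ATTENTIVEFP", "DNN_EXP", "DNN_FUSION"),
    trimnet_exp = mk("GRAPH_TRIMNET", "DNN_EXP", "DNN_FUSION"),
    gcn_cnn_exp = mk("GRAPH_GCN", "CNN_EXP", "DNN_FUSION"),
    fp_dnn_mut = mk("FP_DNN", "DNN_MUT", "DNN_FUSION")
  )
  stopifnot(length(configs) == 16L)
  configs
}

#' Run a benchmark over configurations, split strategies, and seeds
#'
#' For each (configuration, strategy): every seed produces a fresh split;
#' each learning rate in the grid is trained fully and the rate with the
#' best validation MSE is selected; the winner's test metrics are
#' aggregated as mean and standard deviation across seeds. Failed runs are
#' recorded as failed rows and the harness continues.
#'
#' @param suite Named list of `model_config`s (e.g. [benchmark_suite()]).
#' @param drdata A cleaned `dr_data` handle.
#' @param strategies Character vector of split strategies.
#' @param seeds Integer vector of split/training seeds.
#' @param lr_grid Learning-rate grid (default the tuning grid
#'   `c(1e-3, 1e-4, 1e-5)`).
#' @param epochs Training epochs per run.
#' @param batch_size Batch size.
#' @param fractions Split fractions (default 8:1:1).
#' @param out_csv Optional path; the results table is written there as CSV.
#' @param verbose Report progress.
#' @return Data frame with one row per (config, strategy): best lr, mean and
#'   SD of test MSE/R2/PCC across seeds, and a status column. Seed-level
#'   results are attached as the `"seed_detail"` attribute.
#' @export
run_benchmark <- function(suite, drdata, strategies = c("leave_cell_out", "leave_drug_out"),
                          seeds = c(1L, 2L, 3L), lr_grid = c(1e-3, 1e-4, 1e-5),
                          epochs = 100L, batch_size = 32L, weight_decay = 0,
                          fractions = c(0.8, 0.1, 0.1), out_csv = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(drdata, "dr_data"))
  rows <- list()
  details <- list()
  for (cfg_name in names(suite)) {
    config <- suite[[cfg_name]]
    for (strategy in strategies) {
      row <- tryCatch({
        per_seed <- lapply(seeds, function(sd) {
          sp <- split_records(drdata$records, strategy, fractions, seed = sd)
          train_set <- dr_dataset(sp$train, drdata$omics, config)
          val_set <- dr_dataset(sp$val, drdata$omics, config, state = train_set$state)
          test_set <- dr_dataset(sp$test, drdata$omics, config, state = train_set$state)
          dae <- if (config$cell_encoder == "DAE_EXP") {
            pretrain_dae(train_set$cell_matrix, noise_rate = config$hyperparams$dae_noise,
                         epochs = 20L, seed = sd, hp = config$hyperparams)
          } else NULL
          best <- NULL
          for (lr in lr_grid) {
            cfg_s <- config
            cfg_s$seed <- sd
            model <- build_model(cfg_s, train_set, dae_fit = dae)
            run <- train_model(model, train_set, val_set, epochs = epochs,
                               learning_rate = lr, seed = sd, batch_size = batch_size,
                               weight_decay = weight_decay)
            if (is.null(best) || run$best_val_mse < best$run$best_val_mse) {
              best <- list(run = run, lr = lr)
            }
          }
          model <- restore_best(best$run)
          rep <- evaluate_model(model, test_set)
          list(lr = best$lr, mse = rep$mse, r2 = rep$r2, pcc = rep$pcc, seed = sd)
        })
        details[[length(details) + 1L]] <- data.frame(
          config = cfg_name, strategy = strategy,
          seed = vapply(per_seed, function(x) as.numeric(x$seed), 1),
          lr = vapply(per_seed, `[[`, 1, "lr"),
          mse = vapply(per_seed, `[[`, 1, "mse"),
          r2 = vapply(per_seed, `[[`, 1, "r2"),
          pcc = vapply(per_seed, `[[`, 1, "pcc"),
          stringsAsFactors = FALSE
        )
        mse <- vapply(per_seed, `[[`, 1, "mse")
        r2 <- vapply(per_seed, `[[`, 1, "r2")
        pcc <- vapply(per_seed, `[[`, 1, "pcc")
        data.frame(config = cfg_name, strategy = strategy, seed_count = length(seeds),
                   lr = per_seed[[1L]]$lr,
                   mse_mean = mean(mse), mse_sd = stats::sd(mse),
                   r2_mean = mean(r2), r2_sd = stats::sd(r2),
                   pcc_mean = mean(pcc), pcc_sd = stats::sd(pcc),
                   status = "ok", stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(config = cfg_name, strategy = strategy, seed_count = length(seeds),
                   lr = NA_real_, mse_mean = NA_real_, mse_sd = NA_real_,
                   r2_mean = NA_real_, r2_sd = NA_real_, pcc_mean = NA_real_,
                   pcc_sd = NA_real_, status = paste0("failed: ", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
      if (verbose) message(cfg_name, " / ", strategy, ": ", row$status)
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "seed_detail") <- if (length(details)) do.call(rbind, details) else NULL
  if (!is.null(out_csv)) utils::write.csv(res, out_csv, row.names = FALSE)
  res
}
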