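# Dataset featurization and model assembly. A `dr_dataset` pairs cleaned
# response records with precomputed drug features (one per unique drug) and
# a normalised cell matrix, carrying the featurization state (vocabulary,
# per-gene normalisation statistics, gene order) fitted on the training
# split so validation/test data reuse it without leakage.

.drug_modality <- function(drug_encoder) {
  .DRUG_ENCODERS$input_modality[.DRUG_ENCODERS$name == drug_encoder]
}

.cell_modality <- function(cell_encoder) {
  .CELL_ENCODERS$input_modality[.CELL_ENCODERS$name == cell_encoder]
}

#' Instantiate a featurized dataset for a model configuration
#'
#' @param records Cleaned record data frame (one part of a `split_result`).
#' @param omics Named list of `cell_profiles` covering the configuration's
#'   cell modality.
#' @param config A [model_config()].
#' @param state Featurization state from the training dataset; NULL fits a
#'   new state (vocabulary from these records' SMILES, per-gene
#'   normalisation from these records' cells) — pass the training dataset's
#'   `state` when featurizing validation or test records.
#' @return An object of class `dr_dataset`.
#' @export
dr_dataset <- function(records, omics, config, state = NULL) {
  stopifnot(inherits(config, "model_config"), nrow(records) > 0L)
  hp <- config$hyperparams
  dmod <- .drug_modality(config$drug_encoder)
  cmod <- .cell_modality(config$cell_encoder)
  if (!(cmod %in% names(omics))) {
    stop("omics list has no ", cmod, " profiles required by ", config$cell_encoder)
  }
  prof <- omics[[cmod]]
  missing_cells <- setdiff(unique(records$cell_id), prof$cell_ids)
  if (length(missing_cells) > 0L) {
    stop("no ", cmod, " profile for cell(s): ", paste(utils::head(missing_cells, 5L), collapse = ", "))
  }
  uniq <- unique(records[, c("drug_id", "smiles")])

  if (is.null(state)) {
    norm <- fit_normalizer(cell_profiles(
      prof$values[, unique(records$cell_id), drop = FALSE], prof$modality))
    vocab <- if (dmod == "SMILES") build_vocab(uniq$smiles) else NULL
    state <- list(
      drug_modality = dmod, cell_modality = cmod, vocab = vocab,
      normalizer = norm, feature_names = prof$feature_names,
      fp_length = hp$fp_length, fp_radius = hp$fp_radius, max_len = hp$max_len,
      schema = atom_feature_schema()
    )
  } else {
    if (!identical(state$feature_names, prof$feature_names)) {
      stop("feature order of supplied profiles differs from the featurization state")
    }
  }

  drug_features <- lapply(seq_len(nrow(uniq)), function(i) {
    s <- uniq$smiles[i]
    switch(dmod,
      FP = compute_fingerprint(s, L = state$fp_length, radius = state$fp_radius),
      SMILES = tokenize_smiles(s, state$vocab, max_len = state$max_len),
      GRAPH = smiles_to_graph(s))
  })
  names(drug_features) <- uniq$drug_id

  cells <- unique(records$cell_id)
  normed <- apply_normalizer(state$normalizer,
                             cell_profiles(prof$values[, cells, drop = FALSE], prof$modality))
  cell_matrix <- t(normed$values)  # cells x features

  structure(list(records = records, drug_features = drug_features,
                 cell_matrix = cell_matrix, state = state, config = config),
            class = "dr_dataset")
}

#' @export
print.dr_dataset <- function(x, ...) {
  cat("<dr_dataset> ", nrow(x$records), " records, ",
      length(x$drug_features), " drugs (", x$state$drug_modality, "), ",
      nrow(x$cell_matrix), " cells (", x$state$cell_modality, " x ",
      ncol(x$cell_matrix), ")\n", sep = "")
  invisible(x)
}

.dataset_meta <- function(dataset) {
  st <- dataset$state
  list(fp_length = st$fp_length,
       vocab_size = if (!is.null(st$vocab)) st$vocab$vocab_size else NA_integer_,
       d_atom = st$schema$d_atom, d_bond = st$schema$d_bond,
       n_features = stats::setNames(list(ncol(dataset$cell_matrix)), st$cell_modality))
}

#' Build a drug-response model from a configuration
#'
#' Initialises all encoder, fusion, and prediction-head weights (seeded by
#' `config$seed`) against the shapes of a featurized dataset.
#'
#' @param config A [model_config()].
#' @param dataset The training `dr_dataset` (supplies input shapes).
#' @param dae_fit Optional [pretrain_dae()] result whose weights initialise
#'   the `DAE_EXP` encoder.
#' @return An object of class `dr_model` with `params`, `config`, `meta`.
#' @export
build_model <- function(config, dataset, dae_fit = NULL) {
  stopifnot(inherits(config, "model_config"), inherits(dataset, "dr_dataset"))
  meta <- .dataset_meta(dataset)
  hp <- config$hyperparams
  set.seed(config$seed)
  params <- list(
    drug = drug_encoder_init(config$drug_encoder, meta, hp),
    cell = cell_encoder_init(config$cell_encoder, meta, hp)
  )
  if (config$fusion == "MHA_FUSION") params$fusion <- mha_fusion_init(hp$d, hp)
  head_width <- if (config$fusion == "DNN_FUSION" && hp$combine == "concat") 2L * hp$d else hp$d
  params$head <- predict_head_init(head_width, hp)
  if (!is.null(dae_fit)) {
    if (config$cell_encoder != "DAE_EXP") stop("dae_fit supplied for a non-DAE cell encoder")
    if (dae_fit$params$n_in != meta$n_features[["EXP"]]) {
      stop("DAE was pre-trained on ", dae_fit$params$n_in, " genes; dataset has ",
           meta$n_features[["EXP"]])
    }
    stopifnot(ncol(dae_fit$params$enc[[length(dae_fit$params$enc)]]$W$val) == hp$d)
    params$cell <- dae_fit$params
  }
  structure(list(params = params, config = config, meta = meta), class = "dr_model")
}

#' @export
print.dr_model <- function(x, ...) {
  n_par <- sum(vapply(ad_collect_params(x$params), function(p) length(p$val), 1))
  cat("<dr_model> ", x$config$name, " (", n_par, " parameters)\n", sep = "")
  invisible(x)
}

# Forward pass over a set of record indices. Drug and cell encodings are
# computed once per unique drug/cell in the batch and reused.
model_forward <- function(model, dataset, idx = seq_len(nrow(dataset$records))) {
  hp <- model$config$hyperparams
  recs <- dataset$records[idx, , drop = FALSE]
  u_drugs <- unique(recs$drug_id)
  u_cells <- unique(recs$cell_id)
  drug_outs <- lapply(u_drugs, function(dd) {
    encode_drug(model$config$drug_encoder, model$params$drug,
                dataset$drug_features[[dd]], hp)
  })
  names(drug_outs) <- u_drugs
  cellH <- encode_cell(model$config$cell_encoder, model$params$cell,
                       dataset$cell_matrix[u_cells, , drop = FALSE], hp)
  preds <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    cvec <- ad_rows(cellH, match(recs$cell_id[i], u_cells))
    dout <- drug_outs[[recs$drug_id[i]]]
    fused <- if (model$config$fusion == "MHA_FUSION") {
      mha_fuse(model$params$fusion, cvec, dout, heads = hp$heads)
    } else {
      dnn_fuse(dout, cvec, pooling = hp$pooling, combine = hp$combine)
    }
    preds[[i]] <- fused
  }
  out <- predict_head(model$params$head, ad_rbind(preds))
  list(pred = out, targets = recs$response)
}

#' Predict responses for dataset records (no training)
#'
#' @param model A `dr_model`.
#' @param dataset A `dr_dataset` featurized with the model's training state.
#' @param idx Record indices (default all).
#' @return Numeric vector of predictions.
#' @export
model_predict <- function(model, dataset, idx = seq_len(nrow(dataset$records))) {
  ad_begin()
  fw <- model_forward(model, dataset, idx)
  .ad$recording <- FALSE
  drop(fw$pred$val)
}

# ---- checkpoints -----------------------------------------------------------

#' Save a trained model as a single-file checkpoint
#'
#' The checkpoint carries the weights, the model configuration, and the full
#' featurization state (token vocabulary, gene order, normalisation
#' statistics, cell matrix), so inference reproduces training-time
#' featurization exactly.
#'
#' @param model A `dr_model`.
#' @param dataset The training `dr_dataset` (for state and cell profiles).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(model, dataset, path) {
  ck <- list(format_version = 1L,
             config = model$config,
             param_values = ad_param_values(model$params),
             state = dataset$state,
             cell_matrix = dataset$cell_matrix,
             meta = model$meta)
  saveRDS(ck, path)
  invisible(path)
}

#' Load a checkpoint and rebuild the model
#'
#' @param path Checkpoint file from [write_checkpoint()].
#' @return List with `model` (a `dr_model` carrying the saved weights),
#'   `state`, and `cell_matrix`.
#' @export
read_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$format_version) || ck$format_version != 1L) {
    stop("unsupported checkpoint format")
  }
  hp <- ck$config$hyperparams
  params <- list(
    drug = drug_encoder_init(ck$config$drug_encoder, ck$meta, hp),
    cell = cell_encoder_init(ck$config$cell_encoder, ck$meta, hp)
  )
  if (ck$config$fusion == "MHA_FUSION") params$fusion <- mha_fusion_init(hp$d, hp)
  head_width <- if (ck$config$fusion == "DNN_FUSION" && hp$combine == "concat") 2L * hp$d else hp$d
  params$head <- predict_head_init(head_width, hp)
  ad_param_load(params, ck$param_values)
  model <- structure(list(params = params, config = ck$config, meta = ck$meta),
                     class = "dr_model")
  list(model = model, state = ck$state, cell_matrix = ck$cell_matrix)
}
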