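# Fusion of drug and cell encodings, the prediction head, and the model
# factory that enumerates valid (drug encoder, cell encoder, fusion)
# configurations.
#
# Two fusion modules: DNN_FUSION pools a drug sequence into one vector
# (masked mean or max) and combines it with the cell vector by addition or
# concatenation; MHA_FUSION treats the cell vector as the attention query Q
# over the drug's token/atom vectors acting as keys K and values V,
# softmax(Q K^T / sqrt(d_k)) V, with masked positions receiving exactly
# zero weight via an additive -1e9 logit.

.FUSIONS <- data.frame(
  name = c("DNN_FUSION", "MHA_FUSION"),
  needs_sequence = c(FALSE, TRUE),
  stringsAsFactors = FALSE
)

#' Registry of fusion modules
#' @return A data frame with columns `name`, `needs_sequence` (2 rows).
#' @export
fusion_registry <- function() .FUSIONS

#' Scaled dot-product attention with a single query
#'
#' The computational core of the attention fusion:
#' `softmax(Q K^T / sqrt(d_k)) V` for one query row. Masked key positions
#' get an additive -1e9 logit, which underflows to an exactly-zero softmax
#' weight.
#'
#' @param Q 1 x d_k query (matrix or autodiff node).
#' @param K,V T x d_k key and value matrices (or nodes).
#' @param mask Binary length-T vector of real positions (default all real).
#' @return List with `out` (1 x d_k node) and `weights` (numeric length-T
#'   attention weights).
#' @export
attention_core <- function(Q, K, V, mask = NULL) {
  dk <- ncol(.v(K))
  Tn <- nrow(.v(K))
  if (is.null(mask)) mask <- rep(1, Tn)
  if (sum(mask) < 1) stop("attention over an all-masked sequence is undefined")
  scores <- ad_scale(ad_matmul(Q, ad_t(K)), 1 / sqrt(dk))  # 1 x T
  mask_add <- matrix(ifelse(mask > 0, 0, -1e9), 1L)
  alpha <- ad_softmax_rows(ad_add(scores, ad_const(mask_add)))
  list(out = ad_matmul(alpha, V), weights = drop(alpha$val))
}

mha_fusion_init <- function(d, hp) {
  list(Wq = nn_linear_init(d, d), Wk = nn_linear_init(d, d),
       Wv = nn_linear_init(d, d), Wo = nn_linear_init(d, d))
}

#' Multi-head attention fusion of a cell vector over a drug sequence
#'
#' The cell vector acts as the query; the drug sequence supplies keys and
#' values. Each head attends over real sequence positions with weights that
#' sum to one; per-head outputs are concatenated and projected back to d.
#'
#' @param params Parameters from `mha_fusion_init` (learned projections).
#' @param cell_vec 1 x d autodiff node.
#' @param drug_out An `encoder_output` of kind `"sequence"`.
#' @param heads Number of attention heads (must divide d).
#' @return A 1 x d node with attribute `"weights"` (heads x T matrix of
#'   attention weights).
#' @export
mha_fuse <- function(params, cell_vec, drug_out, heads = 4L) {
  if (!inherits(drug_out, "encoder_output") || drug_out$kind != "sequence") {
    stop("MHA fusion requires a sequence drug encoding")
  }
  d <- ncol(.v(cell_vec))
  if (d %% heads != 0L) stop("d (", d, ") must be divisible by heads (", heads, ")")
  dh <- d %/% heads
  q <- nn_linear(params$Wq, cell_vec)
  K <- nn_linear(params$Wk, drug_out$vectors)
  V <- nn_linear(params$Wv, drug_out$vectors)
  outs <- vector("list", heads)
  W <- matrix(0, heads, nrow(.v(K)))
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    att <- attention_core(ad_cols(q, cols), ad_cols(K, cols), ad_cols(V, cols),
                          mask = drug_out$mask)
    outs[[h]] <- att$out
    W[h, ] <- att$weights
  }
  out <- nn_linear(params$Wo, ad_cbind(outs))
  attr(out, "weights") <- W
  out
}

#' Pooled feed-forward fusion
#'
#' A sequence drug encoding is condensed to one vector by masked global
#' average or maximum pooling over real positions; the drug and cell vectors
#' are then added (equal widths required) or concatenated.
#'
#' @param drug_out An `encoder_output` (single or sequence).
#' @param cell_vec 1 x d node.
#' @param pooling `"mean"` or `"max"` (sequence inputs only).
#' @param combine `"add"` or `"concat"`.
#' @return A 1 x d (`add`) or 1 x 2d (`concat`) node.
#' @export
dnn_fuse <- function(drug_out, cell_vec, pooling = c("mean", "max"),
                     combine = c("concat", "add")) {
  pooling <- match.arg(pooling)
  combine <- match.arg(combine)
  stopifnot(inherits(drug_out, "encoder_output"))
  dvec <- if (drug_out$kind == "single") {
    drug_out$vectors
  } else {
    real <- which(drug_out$mask > 0)
    if (length(real) == 0L) stop("cannot pool an all-masked sequence")
    if (pooling == "mean") {
      w <- matrix(0, 1L, nrow(.v(drug_out$vectors)))
      w[1L, real] <- 1 / length(real)
      ad_matmul(ad_const(w), drug_out$vectors)
    } else {
      ad_colmax(drug_out$vectors, rows = real)
    }
  }
  if (combine == "add") {
    if (ncol(.v(dvec)) != ncol(.v(cell_vec))) {
      stop("configuration error: 'add' combine requires equal drug/cell widths (",
           ncol(.v(dvec)), " vs ", ncol(.v(cell_vec)), ")")
    }
    ad_add(dvec, cell_vec)
  } else {
    ad_cbind(list(dvec, cell_vec))
  }
}

predict_head_init <- function(width, hp) nn_mlp_init(c(width, hp$head_hidden, 1L))

#' Prediction head: fused vector to scalar response
#'
#' Two linear layers with a ReLU between and no output activation (ln-IC50 /
#' AUC / ActArea responses are unbounded).
#'
#' @param params Parameters from `predict_head_init`.
#' @param fused n x width node of fused representations.
#' @return n x 1 node of predicted responses.
#' @export
predict_head <- function(params, fused) {
  out <- nn_mlp(params, fused)
  if (!all(is.finite(out$val))) {
    stop("non-finite activation in prediction head (input range [",
         paste(signif(range(.v(fused)), 4), collapse = ", "), "])")
  }
  out
}

#' Is a (drug encoder, cell encoder, fusion) triple buildable?
#'
#' DNN fusion accepts every drug encoder (9 x 9 pairs); attention fusion
#' requires a sequence drug encoding (6 of the 9 drug encoders), giving
#' 81 + 54 = 135 valid configurations.
#'
#' @param drug,cell,fusion Registry names.
#' @return Logical.
#' @export
is_valid_combination <- function(drug, cell, fusion) {
  de <- .DRUG_ENCODERS[.DRUG_ENCODERS$name == drug, ]
  if (nrow(de) == 0L) stop("unknown drug encoder: ", drug)
  if (!(cell %in% .CELL_ENCODERS$name)) stop("unknown cell encoder: ", cell)
  fu <- .FUSIONS[.FUSIONS$name == fusion, ]
  if (nrow(fu) == 0L) stop("unknown fusion module: ", fusion)
  !fu$needs_sequence || de$output_kind == "sequence"
}

#' Construct a model configuration
#'
#' @param drug_encoder,cell_encoder,fusion Registry names forming a valid
#'   combination.
#' @param hyperparams Hyperparameter list ([default_hyperparams()]).
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `model_config`.
#' @export
model_config <- function(drug_encoder, cell_encoder, fusion,
                         hyperparams = default_hyperparams(), seed = 1L) {
  if (!is_valid_combination(drug_encoder, cell_encoder, fusion)) {
    stop("invalid combination: ", drug_encoder, " + ", cell_encoder, " + ", fusion,
         " (attention fusion needs a sequence drug encoder)")
  }
  structure(list(drug_encoder = drug_encoder, cell_encoder = cell_encoder,
                 fusion = fusion, hyperparams = hyperparams, seed = seed,
                 name = paste(drug_encoder, cell_encoder, fusion, sep = "+")),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> ", x$name, " (d=", x$hyperparams$d, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Enumerate all valid model configurations
#'
#' @param hyperparams Hyperparameters shared by every configuration.
#' @param seed Seed recorded in every configuration.
#' @return A list of 135 `model_config` objects in stable registry order
#'   (drug encoder outermost, then cell encoder, then fusion).
#' @export
enumerate_models <- function(hyperparams = default_hyperparams(), seed = 1L) {
  out <- list()
  for (de in .DRUG_ENCODERS$name) {
    for (ce in .CELL_ENCODERS$name) {
      for (fu in .FUSIONS$name) {
        if (is_valid_combination(de, ce, fu)) {
          out[[length(out) + 1L]] <- model_config(de, ce, fu, hyperparams, seed)
        }
      }
    }
  }
  out
}
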