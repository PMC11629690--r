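# The nine cell encoders: feed-forward (DNN) and convolutional (CNN)
# encoders over each of the four omics modalities, plus a denoising
# autoencoder (DAE) over expression. All cell encoders compress a profile
# into a single 1 x d vector.

.CELL_ENCODERS <- data.frame(
  name = c("DNN_EXP", "DNN_PES", "DNN_MUT", "DNN_CNV",
           "CNN_EXP", "CNN_PES", "CNN_MUT", "CNN_CNV", "DAE_EXP"),
  input_modality = c("EXP", "PES", "MUT", "CNV", "EXP", "PES", "MUT", "CNV", "EXP"),
  stringsAsFactors = FALSE
)

#' Registry of cell encoders
#'
#' Four feed-forward and four convolutional encoders (one per omics
#' modality) plus a denoising autoencoder over expression, whose encoder
#' half is pre-trained by reconstructing corrupted profiles and whose hidden
#' vector is used as the cell encoding.
#'
#' @return A data frame with columns `name`, `input_modality` (9 rows).
#' @export
cell_encoder_registry <- function() .CELL_ENCODERS

# Convolution output length for "valid" padding.
.conv_len <- function(Tn, k, stride) (Tn - k) %/% stride + 1L

cell_encoder_init <- function(name, meta, hp) {
  d <- hp$d
  G <- meta$n_features[[.CELL_ENCODERS$input_modality[.CELL_ENCODERS$name == name]]]
  if (is.null(G)) stop("no feature count available for cell encoder ", name)
  kind <- sub("_.*$", "", name)
  if (kind == "DNN") {
    return(list(mlp = nn_mlp_init(c(G, hp$dnn_hidden, d)), n_in = G))
  }
  if (kind == "CNN") {
    k <- hp$cell_cnn_kernel; s <- hp$cell_cnn_stride; ch <- hp$cell_cnn_channels
    t1 <- .conv_len(G, k, s)
    t2 <- .conv_len(t1, k, s)
    if (t2 < 1L) stop("profile length ", G, " too short for the CNN cell encoder")
    return(list(conv1 = nn_conv1d_init(1L, ch, k), conv2 = nn_conv1d_init(ch, ch, k),
                head = nn_linear_init(t2 * ch, d), n_in = G, t2 = t2, ch = ch))
  }
  # DAE: encoder G -> hidden -> d, decoder d -> hidden -> G
  list(enc = nn_mlp_init(c(G, hp$dae_hidden, d)), dec = nn_mlp_init(c(d, hp$dae_hidden, G)),
       n_in = G)
}

#' Encode cell profiles with a named encoder
#'
#' @param name Encoder name from [cell_encoder_registry()].
#' @param params Parameters from the model factory (for `DAE_EXP`,
#'   optionally the pre-trained weights from [pretrain_dae()]).
#' @param X Numeric matrix (cells x features) or an autodiff node; feature
#'   order must match the training-time order.
#' @param hp Hyperparameter list.
#' @return An autodiff node of shape cells x d (a 1 x d single vector per
#'   cell).
#' @export
encode_cell <- function(name, params, X, hp = default_hyperparams()) {
  if (!(name %in% .CELL_ENCODERS$name)) stop("unknown cell encoder: ", name)
  Xv <- .v(X)
  if (ncol(Xv) != params$n_in) {
    stop("configuration error: cell encoder ", name, " was built for ",
         params$n_in, " features, got ", ncol(Xv))
  }
  Xn <- if (is_ad(X)) X else ad_const(X)
  kind <- sub("_.*$", "", name)
  if (kind == "DNN") return(nn_mlp(params$mlp, Xn))
  if (kind == "DAE") return(nn_mlp(params$enc, Xn))
  # CNN over the (fixed, serialized) gene order; one sample at a time
  rows <- lapply(seq_len(nrow(Xv)), function(i) {
    x <- ad_t(ad_rows(Xn, i))  # G x 1
    h <- ad_relu(nn_conv1d(params$conv1, x, stride = hp$cell_cnn_stride, pad = "valid"))
    h <- ad_relu(nn_conv1d(params$conv2, h, stride = hp$cell_cnn_stride, pad = "valid"))
    flat <- ad_cbind(lapply(seq_len(params$t2), function(t) ad_rows(h, t)))
    nn_linear(params$head, flat)
  })
  ad_rbind(rows)
}

#' Pre-train the denoising autoencoder on expression profiles
#'
#' Each training input is corrupted by masking noise (entries set to zero
#' independently with probability `noise_rate`; `noise = "gaussian"` adds
#' N(0, noise_rate) instead) and the autoencoder minimises the mean squared
#' reconstruction error against the clean profile. The encoder half then
#' drives `DAE_EXP` in [encode_cell()]. Run this on training-split cells
#' only.
#'
#' @param exp_matrix Numeric matrix, cells x genes (training cells only).
#' @param noise_rate Corruption probability in `[0, 1)` (default 0.2);
#'   0 reduces to a plain autoencoder.
#' @param epochs Number of full-batch epochs (must be >= 1).
#' @param seed Integer seed covering weight init and noise draws.
#' @param hp Hyperparameter list (`d`, `dae_hidden`).
#' @param lr Adam learning rate.
#' @return An object of class `dae_fit`: `params` (with `n_in`), `history`
#'   (per-epoch training reconstruction loss on corrupted inputs), and
#'   `noise_rate`.
#' @export
pretrain_dae <- function(exp_matrix, noise_rate = 0.2, epochs = 30L, seed = 1L,
                         hp = default_hyperparams(), lr = 1e-3,
                         noise = c("masking", "gaussian")) {
  noise <- match.arg(noise)
  X <- as.matrix(exp_matrix)
  stopifnot(nrow(X) >= 2L, noise_rate >= 0, noise_rate < 1)
  if (epochs < 1L) stop("pretrain_dae: epochs must be >= 1 (no silent success)")
  if (stats::sd(X) < 1e-12) warning("pretrain_dae: constant input matrix; reconstruction is degenerate")
  set.seed(seed)
  params <- cell_encoder_init("DAE_EXP", list(n_features = list(EXP = ncol(X))), hp)
  params$n_in <- ncol(X)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    Xc <- if (noise == "masking") {
      X * (matrix(stats::runif(length(X)), nrow(X)) >= noise_rate)
    } else {
      X + matrix(stats::rnorm(length(X), sd = noise_rate), nrow(X))
    }
    ad_begin()
    h <- nn_mlp(params$enc, ad_const(Xc))
    recon <- nn_mlp(params$dec, h)
    loss <- ad_mse_loss(recon, X)
    history[ep] <- loss$val[1L]
    ad_zero_grad(params)
    ad_backward(loss)
    adam_step(params, lr, ep)
  }
  structure(list(params = params, history = history, noise_rate = noise_rate,
                 noise = noise, seed = seed),
            class = "dae_fit")
}

#' Reconstruction loss of a DAE on clean (uncorrupted) inputs
#'
#' Pre-training corrupts inputs; evaluation must not, so this helper always
#' feeds the clean matrix through encoder and decoder.
#'
#' @param fit A `dae_fit` (or its `params`).
#' @param X Cells x genes matrix.
#' @return Mean squared reconstruction error (scalar).
#' @export
dae_reconstruction_loss <- function(fit, X) {
  params <- if (inherits(fit, "dae_fit")) fit$params else fit
  ad_begin()
  recon <- nn_mlp(params$dec, nn_mlp(params$enc, ad_const(as.matrix(X))))
  loss <- ad_mse_loss(recon, as.matrix(X))
  .ad$recording <- FALSE
  loss$val[1L]
}
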