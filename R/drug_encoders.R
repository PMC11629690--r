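# The nine drug encoders behind one registry and one output contract.
# Every encoder maps a drug feature to an `encoder_output`: either a single
# 1 x d vector (kind "single") or a T x d sequence with a mask (kind
# "sequence"), where T is the token count (SMILES) or atom count (graph).
# Padded token positions are stripped before encoding, so padded values can
# never influence any output row.

.DRUG_ENCODERS <- data.frame(
  name = c("FP_DNN", "SMILES_CNN", "SMILES_GRU", "SMILES_LSTM",
           "GRAPH_GCN", "GRAPH_GAT", "GRAPH_MPG",
           "GRAPH_ATTENTIVEFP", "GRAPH_TRIMNET"),
  input_modality = c("FP", "SMILES", "SMILES", "SMILES",
                     "GRAPH", "GRAPH", "GRAPH", "GRAPH", "GRAPH"),
  output_kind = c("single", "sequence", "sequence", "sequence",
                  "sequence", "sequence", "sequence", "single", "single"),
  stringsAsFactors = FALSE
)

#' Registry of drug encoders
#'
#' Nine encoders across three input modalities: a feed-forward network over
#' fingerprints; convolutional and recurrent (GRU/LSTM) encoders over SMILES
#' token sequences; and five graph neural networks (GCN, GAT, a
#' message-passing network with edge features, AttentiveFP, TrimNet) over
#' molecular graphs. AttentiveFP and TrimNet carry built-in attention
#' readouts and therefore emit a single vector; the remaining SMILES/graph
#' encoders emit one vector per token or atom.
#'
#' @return A data frame with columns `name`, `input_modality`, `output_kind`
#'   (9 rows).
#' @export
drug_encoder_registry <- function() .DRUG_ENCODERS

#' Default encoder/fusion hyperparameters
#'
#' @param d Shared encoder output width consumed by fusion (default 128).
#' @param embed_dim Embedding width for SMILES tokens and atoms (default 64).
#' @param ... Overrides for any default.
#' @return Named list of hyperparameters.
#' @export
default_hyperparams <- function(d = 128L, embed_dim = 64L, ...) {
  hp <- list(
    d = d, embed_dim = embed_dim,
    fp_length = 1024L, fp_radius = 2L, fp_hidden = 512L,
    max_len = 200L,
    cnn_layers = 3L, cnn_kernel = 7L,
    rnn_hidden = 64L,
    gnn_layers = 3L, gat_heads = 2L,
    readout_steps = 2L,
    dnn_hidden = c(512L, 128L),
    cell_cnn_kernel = 9L, cell_cnn_stride = 2L, cell_cnn_channels = 8L,
    dae_hidden = 512L, dae_noise = 0.2,
    heads = 4L, pooling = "mean", combine = "concat",
    head_hidden = 64L
  )
  dots <- list(...)
  hp[names(dots)] <- dots
  hp
}

#' Construct an encoder output container
#' @keywords internal
encoder_output <- function(kind, vectors, mask = NULL) {
  structure(list(kind = kind, vectors = vectors, mask = mask), class = "encoder_output")
}

# ---- parameter initialisers ------------------------------------------------

drug_encoder_init <- function(name, meta, hp) {
  d <- hp$d; e <- hp$embed_dim
  switch(name,
    FP_DNN = list(mlp = nn_mlp_init(c(meta$fp_length, hp$fp_hidden, d))),
    SMILES_CNN = {
      chans <- c(e, rep(d, hp$cnn_layers))
      list(emb = nn_embedding_init(meta$vocab_size, e),
           convs = lapply(seq_len(hp$cnn_layers), function(i) nn_conv1d_init(chans[i], chans[i + 1L], hp$cnn_kernel)))
    },
    SMILES_GRU = list(emb = nn_embedding_init(meta$vocab_size, e),
                      fwd = nn_gru_init(e, hp$rnn_hidden), bwd = nn_gru_init(e, hp$rnn_hidden),
                      proj = nn_linear_init(2L * hp$rnn_hidden, d)),
    SMILES_LSTM = list(emb = nn_embedding_init(meta$vocab_size, e),
                       fwd = nn_lstm_init(e, hp$rnn_hidden), bwd = nn_lstm_init(e, hp$rnn_hidden),
                       proj = nn_linear_init(2L * hp$rnn_hidden, d)),
    GRAPH_GCN = {
      widths <- c(e, rep(d, hp$gnn_layers))
      list(emb = nn_linear_init(meta$d_atom, e),
           layers = lapply(seq_len(hp$gnn_layers), function(i) nn_linear_init(widths[i], widths[i + 1L])))
    },
    GRAPH_GAT = {
      widths <- c(e, rep(d, hp$gnn_layers))
      list(emb = nn_linear_init(meta$d_atom, e),
           layers = lapply(seq_len(hp$gnn_layers), function(i) {
             dh <- widths[i + 1L] %/% hp$gat_heads
             list(heads = lapply(seq_len(hp$gat_heads), function(h) {
               list(W = nn_linear_init(widths[i], dh),
                    a_src = ad_param(.init_mat(dh, 1L)), a_dst = ad_param(.init_mat(dh, 1L)))
             }))
           }))
    },
    GRAPH_MPG = {
      widths <- c(e, rep(d, hp$gnn_layers))
      list(emb = nn_linear_init(meta$d_atom, e),
           layers = lapply(seq_len(hp$gnn_layers), function(i) {
             list(msg = nn_linear_init(widths[i] + meta$d_bond, widths[i + 1L]),
                  upd = nn_linear_init(widths[i] + widths[i + 1L], widths[i + 1L]))
           }))
    },
    GRAPH_ATTENTIVEFP = list(
      emb = nn_linear_init(meta$d_atom, d),
      prop = lapply(seq_len(hp$readout_steps), function(i) {
        list(att = nn_linear_init(2L * d, 1L), val = nn_linear_init(d, d), gru = nn_gru_init(d, d))
      }),
      read = lapply(seq_len(hp$readout_steps), function(i) {
        list(att = nn_linear_init(2L * d, 1L), gru = nn_gru_init(d, d))
      })
    ),
    GRAPH_TRIMNET = list(
      emb = nn_linear_init(meta$d_atom, d),
      prop = lapply(seq_len(hp$readout_steps), function(i) {
        list(att = nn_linear_init(2L * d + meta$d_bond, 1L),
             val = nn_linear_init(2L * d + meta$d_bond, d),
             gru = nn_gru_init(d, d))
      }),
      read = lapply(seq_len(hp$readout_steps), function(i) {
        list(att = nn_linear_init(2L * d, 1L), gru = nn_gru_init(d, d))
      })
    ),
    stop("unknown drug encoder: ", name)
  )
}

# ---- forward passes --------------------------------------------------------

# Symmetric-normalised adjacency with self loops, as a constant matrix.
.gcn_adj <- function(graph) {
  n <- nrow(graph$node_features)
  A <- diag(n)
  if (nrow(graph$edge_index) > 0L) A[graph$edge_index] <- 1
  dinv <- 1 / sqrt(rowSums(A))
  A * (dinv %o% dinv)
}

# Dense additive attention mask: 0 on (self + neighbour) entries, -1e9 off.
.attn_mask <- function(graph) {
  n <- nrow(graph$node_features)
  M <- matrix(-1e9, n, n)
  diag(M) <- 0
  if (nrow(graph$edge_index) > 0L) M[graph$edge_index] <- 0
  M
}

.gat_layer <- function(layer, H, mask_add, n) {
  outs <- lapply(layer$heads, function(hd) {
    HW <- nn_linear(hd$W, H)
    s1 <- ad_matmul(HW, hd$a_src)                       # n x 1
    s2 <- ad_matmul(HW, hd$a_dst)                       # n x 1
    E <- ad_add(ad_matmul(s1, ad_const(matrix(1, 1L, n))),
                ad_matmul(ad_const(matrix(1, n, 1L)), ad_t(s2)))
    alpha <- ad_softmax_rows(ad_add(ad_leaky_relu(E), ad_const(mask_add)))
    ad_matmul(alpha, HW)
  })
  ad_relu(ad_cbind(outs))
}

# Row-wise attention over atoms from a 1 x d summary vector; returns the
# softmax-weighted combination of H's rows (attentive readout step).
.readout_attend <- function(att_p, s, H, n) {
  Srep <- ad_matmul(ad_const(matrix(1, n, 1L)), s)          # n x d
  scores <- ad_leaky_relu(nn_linear(att_p, ad_cbind(list(Srep, H))))  # n x 1
  alpha <- ad_softmax_rows(ad_t(scores))                    # 1 x n
  ad_matmul(alpha, H)                                       # 1 x d
}

#' Encode one drug feature with a named encoder
#'
#' @param name Encoder name from [drug_encoder_registry()].
#' @param params Parameters from the model factory (learned weights).
#' @param feature A `fingerprint_vector`, `token_sequence`, or
#'   `molecular_graph` matching the encoder's input modality.
#' @param hp Hyperparameter list ([default_hyperparams()]).
#' @return An `encoder_output` (1 x d single vector, or T x d sequence with
#'   an all-ones mask over real positions).
#' @export
encode_drug <- function(name, params, feature, hp = default_hyperparams()) {
  spec <- .DRUG_ENCODERS[.DRUG_ENCODERS$name == name, ]
  if (nrow(spec) == 0L) stop("unknown drug encoder: ", name)
  modality <- switch(class(feature)[1L],
    fingerprint_vector = "FP", token_sequence = "SMILES", molecular_graph = "GRAPH",
    stop("unrecognised drug feature of class ", class(feature)[1L]))
  if (modality != spec$input_modality) {
    stop("configuration error: encoder ", name, " expects ", spec$input_modality,
         " features, got ", modality)
  }
  d <- hp$d
  if (name == "FP_DNN") {
    x <- ad_const(matrix(feature$bits, 1L))
    return(encoder_output("single", nn_mlp(params$mlp, x)))
  }
  if (modality == "SMILES") {
    ids <- feature$token_ids[seq_len(feature$n_real)]
    if (length(ids) == 0L) stop("empty token sequence cannot be encoded")
    X <- nn_embedding(params$emb, ids)
    H <- switch(name,
      SMILES_CNN = {
        for (cv in params$convs) X <- ad_relu(nn_conv1d(cv, X, pad = "same"))
        X
      },
      SMILES_GRU = {
        hf <- nn_gru_seq(params$fwd, X)
        hb <- nn_gru_seq(params$bwd, X, reverse = TRUE)
        nn_linear(params$proj, ad_cbind(list(hf, hb)))
      },
      SMILES_LSTM = {
        hf <- nn_lstm_seq(params$fwd, X)
        hb <- nn_lstm_seq(params$bwd, X, reverse = TRUE)
        nn_linear(params$proj, ad_cbind(list(hf, hb)))
      })
    return(encoder_output("sequence", H, mask = rep(1, length(ids))))
  }
  # graph encoders
  graph <- feature
  n <- nrow(graph$node_features)
  if (n == 0L) stop("empty molecular graph cannot be encoded")
  if (name == "GRAPH_GCN") {
    Ahat <- ad_const(.gcn_adj(graph))
    H <- nn_linear(params$emb, ad_const(graph$node_features))
    for (ly in params$layers) H <- ad_relu(nn_linear(ly, ad_matmul(Ahat, H)))
    return(encoder_output("sequence", H, mask = rep(1, n)))
  }
  if (name == "GRAPH_GAT") {
    mask_add <- .attn_mask(graph)
    H <- nn_linear(params$emb, ad_const(graph$node_features))
    for (ly in params$layers) H <- .gat_layer(ly, H, mask_add, n)
    return(encoder_output("sequence", H, mask = rep(1, n)))
  }
  if (name == "GRAPH_MPG") {
    H <- nn_linear(params$emb, ad_const(graph$node_features))
    ne <- nrow(graph$edge_index)
    agg <- NULL
    if (ne > 0L) {
      agg <- matrix(0, n, ne)
      agg[cbind(graph$edge_index[, 2L], seq_len(ne))] <- 1
    }
    for (ly in params$layers) {
      m_agg <- if (ne > 0L) {
        Hsrc <- ad_rows(H, graph$edge_index[, 1L])
        M <- ad_relu(nn_linear(ly$msg, ad_cbind(list(Hsrc, ad_const(graph$edge_features)))))
        ad_matmul(ad_const(agg), M)
      } else ad_const(matrix(0, n, ncol(ly$msg$W$val)))
      H <- ad_relu(nn_linear(ly$upd, ad_cbind(list(H, m_agg))))
    }
    return(encoder_output("sequence", H, mask = rep(1, n)))
  }
  if (name == "GRAPH_ATTENTIVEFP") {
    mask_add <- .attn_mask(graph)
    H <- ad_relu(nn_linear(params$emb, ad_const(graph$node_features)))
    ones_n <- matrix(1, n, 1L)
    for (st in params$prop) {
      # neighbour attention: score(i, j) from [h_i, h_j], dense with mask
      S1 <- nn_linear(st$att, ad_cbind(list(H, ad_const(matrix(0, n, d)))))  # contribution of h_i
      S2 <- nn_linear(st$att, ad_cbind(list(ad_const(matrix(0, n, d)), H)))  # contribution of h_j
      E <- ad_add(ad_matmul(S1, ad_const(matrix(1, 1L, n))),
                  ad_matmul(ad_const(ones_n), ad_t(S2)))
      alpha <- ad_softmax_rows(ad_add(ad_leaky_relu(E), ad_const(mask_add)))
      ctx <- ad_matmul(alpha, nn_linear(st$val, H))
      H <- nn_gru_cell(st$gru, ctx, H)
    }
    s <- ad_scale(ad_matmul(ad_const(matrix(1 / n, 1L, n)), H), 1)  # mean init
    for (st in params$read) {
      ctx <- .readout_attend(st$att, s, H, n)
      s <- nn_gru_cell(st$gru, ctx, s)
    }
    return(encoder_output("single", s))
  }
  if (name == "GRAPH_TRIMNET") {
    H <- ad_relu(nn_linear(params$emb, ad_const(graph$node_features)))
    ne <- nrow(graph$edge_index)
    agg <- NULL
    if (ne > 0L) {
      agg <- matrix(0, n, ne)
      agg[cbind(graph$edge_index[, 2L], seq_len(ne))] <- 1
    }
    for (st in params$prop) {
      if (ne > 0L) {
        Hsrc <- ad_rows(H, graph$edge_index[, 1L])
        Hdst <- ad_rows(H, graph$edge_index[, 2L])
        triplet <- ad_cbind(list(Hsrc, ad_const(graph$edge_features), Hdst))
        # softmax over incoming edges of each destination atom
        es <- ad_exp(ad_leaky_relu(nn_linear(st$att, triplet)))      # ne x 1
        den <- ad_matmul(ad_const(agg), es)                          # n x 1
        inv_den <- ad_exp(ad_scale(ad_log(den), -1))
        alpha <- ad_mul(es, ad_rows(inv_den, graph$edge_index[, 2L]))
        alpha_wide <- ad_matmul(alpha, ad_const(matrix(1, 1L, d)))
        M <- ad_mul(ad_tanh(nn_linear(st$val, triplet)), alpha_wide)
        ctx <- ad_matmul(ad_const(agg), M)
      } else ctx <- ad_const(matrix(0, n, d))
      H <- nn_gru_cell(st$gru, ctx, H)
    }
    s <- ad_matmul(ad_const(matrix(1 / n, 1L, n)), H)
    for (st in params$read) {
      ctx <- .readout_attend(st$att, s, H, n)
      s <- nn_gru_cell(st$gru, ctx, s)
    }
    return(encoder_output("single", s))
  }
  stop("unknown drug encoder: ", name)
}

#' Hook for loading externally pre-trained message-passing weights
#'
#' The message-passing graph encoder is implemented architecture-only; this
#' hook loads a compatible nested list of numeric matrices into its
#' parameters when such weights are available.
#'
#' @param params Initialised `GRAPH_MPG` parameters.
#' @param weights Nested list of matrices with the same structure.
#' @return `params`, with values replaced, invisibly.
#' @export
load_mpg_weights <- function(params, weights) {
  ad_param_load(params, weights)
  invisible(params)
}
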