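# Neural-network layers assembled from autodiff primitives. Initialisers
# draw from the session RNG; callers seed before building a model so weight
# initialisation is reproducible.

.init_mat <- function(nin, nout, scale = sqrt(2 / nin)) {
  matrix(stats::rnorm(nin * nout, sd = scale), nin, nout)
}

nn_linear_init <- function(nin, nout) {
  list(W = ad_param(.init_mat(nin, nout)), b = ad_param(matrix(0, 1L, nout)))
}

nn_linear <- function(p, x) ad_add(ad_matmul(x, p$W), p$b)

nn_mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(i) nn_linear_init(sizes[i], sizes[i + 1L]))
}

# ReLU between layers, linear last layer.
nn_mlp <- function(p, x) {
  for (i in seq_along(p)) {
    x <- nn_linear(p[[i]], x)
    if (i < length(p)) x <- ad_relu(x)
  }
  x
}

# Embedding table: row 1 is the padding vector (held at zero by convention of
# never selecting it), token id k maps to row k + 1.
nn_embedding_init <- function(vocab_size, dim) {
  list(E = ad_param(.init_mat(vocab_size + 1L, dim, scale = 0.1)))
}

nn_embedding <- function(p, ids) ad_rows(p$E, ids + 1L)

# 1-D convolution over rows of x (positions x channels) via im2col: each
# output row gathers k input rows and goes through one linear map.
nn_conv1d_init <- function(cin, cout, k) {
  list(W = ad_param(.init_mat(k * cin, cout)), b = ad_param(matrix(0, 1L, cout)), k = k)
}

nn_conv1d <- function(p, x, stride = 1L, pad = c("same", "valid")) {
  pad <- match.arg(pad)
  k <- p$k
  Tn <- nrow(.v(x)); cin <- ncol(.v(x))
  if (pad == "same") {
    pl <- (k - 1L) %/% 2L
    pr <- k - 1L - pl
    x <- ad_rbind(list(matrix(0, pl, cin), x, matrix(0, pr, cin)))
    Tp <- Tn + pl + pr
  } else Tp <- Tn
  starts <- seq(1L, Tp - k + 1L, by = stride)
  pieces <- lapply(seq_len(k) - 1L, function(j) ad_rows(x, starts + j))
  ad_add(ad_matmul(ad_cbind(pieces), p$W), p$b)
}

# ---- recurrent cells -------------------------------------------------------

nn_gru_init <- function(nin, nh) {
  list(
    Wz = ad_param(.init_mat(nin, nh)), Uz = ad_param(.init_mat(nh, nh)), bz = ad_param(matrix(0, 1L, nh)),
    Wr = ad_param(.init_mat(nin, nh)), Ur = ad_param(.init_mat(nh, nh)), br = ad_param(matrix(0, 1L, nh)),
    Wh = ad_param(.init_mat(nin, nh)), Uh = ad_param(.init_mat(nh, nh)), bh = ad_param(matrix(0, 1L, nh)),
    nh = nh
  )
}

nn_gru_cell <- function(p, xt, h) {
  z <- ad_sigmoid(ad_add(ad_add(ad_matmul(xt, p$Wz), ad_matmul(h, p$Uz)), p$bz))
  r <- ad_sigmoid(ad_add(ad_add(ad_matmul(xt, p$Wr), ad_matmul(h, p$Ur)), p$br))
  hh <- ad_tanh(ad_add(ad_add(ad_matmul(xt, p$Wh), ad_matmul(ad_mul(r, h), p$Uh)), p$bh))
  # h' = (1 - z) * h + z * hh
  one <- ad_const(matrix(1, nrow(.v(z)), p$nh))
  ad_add(ad_mul(ad_sub(one, z), h), ad_mul(z, hh))
}

# Run a GRU over a T x nin sequence; returns T x nh hidden states.
nn_gru_seq <- function(p, x, reverse = FALSE) {
  Tn <- nrow(.v(x))
  ord <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  h <- ad_const(matrix(0, 1L, p$nh))
  hs <- vector("list", Tn)
  for (t in ord) {
    h <- nn_gru_cell(p, ad_rows(x, t), h)
    hs[[t]] <- h
  }
  ad_rbind(hs)
}

nn_lstm_init <- function(nin, nh) {
  g <- function() list(W = ad_param(.init_mat(nin, nh)), U = ad_param(.init_mat(nh, nh)), b = ad_param(matrix(0, 1L, nh)))
  list(i = g(), f = g(), o = g(), c = g(), nh = nh)
}

nn_lstm_seq <- function(p, x, reverse = FALSE) {
  Tn <- nrow(.v(x))
  ord <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  h <- ad_const(matrix(0, 1L, p$nh))
  cc <- ad_const(matrix(0, 1L, p$nh))
  gate <- function(q, xt, h) ad_add(ad_add(ad_matmul(xt, q$W), ad_matmul(h, q$U)), q$b)
  hs <- vector("list", Tn)
  for (t in ord) {
    xt <- ad_rows(x, t)
    i <- ad_sigmoid(gate(p$i, xt, h))
    f <- ad_sigmoid(gate(p$f, xt, h))
    o <- ad_sigmoid(gate(p$o, xt, h))
    cand <- ad_tanh(gate(p$c, xt, h))
    cc <- ad_add(ad_mul(f, cc), ad_mul(i, cand))
    h <- ad_mul(o, ad_tanh(cc))
    hs[[t]] <- h
  }
  ad_rbind(hs)
}
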