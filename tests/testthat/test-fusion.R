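test_that("fusion registry has exactly the two fusion modules", {
  reg <- fusion_registry()
  expect_identical(nrow(reg), 2L)
  expect_setequal(reg$name, c("DNN_FUSION", "MHA_FUSION"))
})

test_that("scaled dot-product attention matches the hand-computed example", {
  # Q = [1, 0]; K = V = I(2); d_k = 2 -> logits [1/sqrt(2), 0]
  a <- attention_core(matrix(c(1, 0), 1), diag(2), diag(2))
  w <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(a$weights, c(w, 1 - w), tolerance = 1e-6)
  expect_equal(drop(drpred:::.v(a$out)), c(w, 1 - w), tolerance = 1e-6)
  expect_equal(round(a$weights, 3), c(0.670, 0.330))
})

test_that("attention weights sum to one, vanish on padding, and collapse for T = 1", {
  set.seed(51)
  for (rep in 1:5) {
    Tn <- sample(2:6, 1)
    K <- matrix(rnorm(Tn * 4), Tn, 4)
    mask <- c(rep(1, Tn - 1), 0)
    a <- attention_core(matrix(rnorm(4), 1), K, K, mask = mask)
    expect_equal(sum(a$weights), 1, tolerance = 1e-6)
    expect_identical(a$weights[Tn], 0)  # exact zero on the masked position
  }
  # single real position: weight exactly 1, output equals that value row
  V <- matrix(c(3.5, -2, 7, 9), 2, 2)
  a1 <- attention_core(matrix(c(1, 2), 1), matrix(c(0.3, 0.1, -1, 2), 2, 2),
                       V, mask = c(1, 0))
  expect_identical(a1$weights, c(1, 0))
  expect_identical(drop(drpred:::.v(a1$out)), V[1L, ])
  # identical key rows: uniform weights
  a2 <- attention_core(matrix(rnorm(3), 1), matrix(1, 4, 3), matrix(rnorm(12), 4, 3))
  expect_equal(a2$weights, rep(0.25, 4), tolerance = 1e-12)
  expect_error(attention_core(matrix(0, 1, 2), diag(2), diag(2), mask = c(0, 0)),
               "all-masked")
})

test_that("multi-head fusion obeys the contract and ignores padded positions", {
  hp <- small_hp()
  set.seed(52)
  params <- drpred:::mha_fusion_init(hp$d, hp)
  H <- matrix(rnorm(5 * hp$d), 5, hp$d)
  seq_out <- drpred:::encoder_output("sequence", drpred:::ad_const(H), mask = c(1, 1, 1, 0, 0))
  cellv <- drpred:::ad_const(matrix(rnorm(hp$d), 1))
  drpred:::ad_begin()
  out <- mha_fuse(params, cellv, seq_out, heads = hp$heads)
  W <- attr(out, "weights")
  expect_identical(dim(W), c(hp$heads, 5L))
  expect_equal(rowSums(W), rep(1, hp$heads), tolerance = 1e-6)
  expect_true(all(W[, 4:5] == 0))
  # changing padded rows does not change the fused vector
  H2 <- H; H2[4:5, ] <- 99
  drpred:::ad_begin()
  out2 <- mha_fuse(params, cellv,
                   drpred:::encoder_output("sequence", drpred:::ad_const(H2), mask = c(1, 1, 1, 0, 0)),
                   heads = hp$heads)
  expect_identical(drpred:::.v(out), drpred:::.v(out2))
  # permuting sequence positions (and the mask) leaves the output unchanged
  perm <- c(3, 1, 4, 2, 5)
  drpred:::ad_begin()
  out3 <- mha_fuse(params, cellv,
                   drpred:::encoder_output("sequence", drpred:::ad_const(H[perm, ]),
                                           mask = c(1, 1, 1, 0, 0)[perm]),
                   heads = hp$heads)
  expect_equal(drpred:::.v(out), drpred:::.v(out3), tolerance = 1e-12)
  expect_error(mha_fuse(params, cellv, drpred:::encoder_output("single", cellv)), "sequence")
})

test_that("pooled fusion: masked mean, elementwise max, add and concat", {
  v <- matrix(c(1, 2, 4), 1)
  seq3 <- drpred:::encoder_output("sequence", drpred:::ad_const(rbind(v, v, v)), mask = c(1, 1, 1))
  cellv <- drpred:::ad_const(matrix(c(10, 20, 30), 1))
  drpred:::ad_begin()
  expect_equal(drpred:::.v(dnn_fuse(seq3, cellv, "mean", "add")), v + c(10, 20, 30))
  two <- drpred:::encoder_output("sequence",
                                 drpred:::ad_const(matrix(c(1, 5, 3, 2), 2, byrow = TRUE)),
                                 mask = c(1, 1))
  cell2 <- drpred:::ad_const(matrix(0, 1, 2))
  expect_equal(drpred:::.v(dnn_fuse(two, cell2, "max", "add")), matrix(c(3, 5), 1))
  cc <- dnn_fuse(two, cell2, "mean", "concat")
  expect_identical(ncol(drpred:::.v(cc)), 4L)
  # masked mean equals the brute-force average over real rows only
  H <- matrix(rnorm(12), 4, 3)
  sq <- drpred:::encoder_output("sequence", drpred:::ad_const(H), mask = c(1, 0, 1, 0))
  got <- drpred:::.v(dnn_fuse(sq, drpred:::ad_const(matrix(0, 1, 3)), "mean", "add"))
  expect_equal(drop(got), colMeans(H[c(1, 3), ]), tolerance = 1e-12)
  wide <- drpred:::encoder_output("single", drpred:::ad_const(matrix(0, 1, 5)))
  expect_error(dnn_fuse(wide, cell2, "mean", "add"), "equal drug/cell widths")
})

test_that("the prediction head is the expected affine map on fixed weights", {
  hp <- small_hp(head_hidden = 2L)
  params <- drpred:::predict_head_init(3L, hp)
  drpred:::ad_param_load(params, list(
    list(W = matrix(c(1, 0, -1, 2, 1, 0), 3, 2), b = matrix(c(0.5, -0.5), 1)),
    list(W = matrix(c(2, -3), 2, 1), b = matrix(1, 1, 1))
  ))
  x <- matrix(c(1, 2, 3), 1)
  drpred:::ad_begin()
  got <- drpred:::.v(predict_head(params, drpred:::ad_const(x)))
  h <- pmax(x %*% matrix(c(1, 0, -1, 2, 1, 0), 3, 2) + c(0.5, -0.5), 0)
  expect_equal(drop(got), drop(h %*% c(2, -3) + 1), tolerance = 1e-12)
  # zero weights: output equals the bias
  drpred:::ad_param_load(params, list(
    list(W = matrix(0, 3, 2), b = matrix(0, 1, 2)),
    list(W = matrix(0, 2, 1), b = matrix(4.25, 1, 1))
  ))
  drpred:::ad_begin()
  expect_identical(drop(drpred:::.v(predict_head(params, drpred:::ad_const(x)))), 4.25)
  # batch in, batch out
  drpred:::ad_begin()
  expect_identical(nrow(drpred:::.v(predict_head(params, drpred:::ad_const(matrix(1, 7, 3))))), 7L)
})

test_that("combination validity reproduces the 135-model count", {
  expect_false(is_valid_combination("FP_DNN", "DNN_EXP", "MHA_FUSION"))
  expect_true(is_valid_combination("SMILES_GRU", "DAE_EXP", "MHA_FUSION"))
  expect_true(is_valid_combination("FP_DNN", "DNN_EXP", "DNN_FUSION"))
  expect_error(is_valid_combination("XX", "DNN_EXP", "DNN_FUSION"), "unknown")
  total <- 0L
  for (de in drug_encoder_registry()$name)
    for (ce in cell_encoder_registry()$name)
      for (fu in fusion_registry()$name)
        total <- total + is_valid_combination(de, ce, fu)
  expect_identical(total, 135L)
})

test_that("model enumeration lists exactly the valid triples", {
  models <- enumerate_models()
  expect_length(models, 135L)
  names_ <- vapply(models, `[[`, "", "name")
  expect_identical(anyDuplicated(names_), 0L)
  expect_true("GRAPH_GCN+CNN_EXP+MHA_FUSION" %in% names_)
  expect_false(any(grepl("^(FP_DNN|GRAPH_ATTENTIVEFP|GRAPH_TRIMNET)\\+.*MHA_FUSION$", names_)))
  expect_identical(sum(grepl("MHA_FUSION$", names_)), 54L)
})
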