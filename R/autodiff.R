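# Reverse-mode automatic differentiation over base R matrices.
#
# Every differentiable quantity is an `ad_node`: an environment holding the
# forward value (`val`, always a base matrix), the accumulated gradient
# (`grad`, same shape, NULL until backward reaches it), and a closure `bw`
# that pushes an incoming gradient to the node's parents. Non-leaf nodes are
# recorded on a global tape in creation order; `ad_backward()` walks the tape
# in reverse. Plain numeric matrices may be passed to any op and are treated
# as constants (no gradient is propagated into them).

.ad <- new.env(parent = emptyenv())
.ad$nodes <- list()
.ad$k <- 0L
.ad$recording <- FALSE

#' Start recording a fresh autodiff tape
#'
#' Clears the tape. Call once per forward pass, before any `ad_*` op.
#' @return Invisibly, NULL.
#' @keywords internal
ad_begin <- function() {
  .ad$nodes <- vector("list", 256L)
  .ad$k <- 0L
  .ad$recording <- TRUE
  invisible(NULL)
}

.ad_record <- function(node) {
  if (!.ad$recording) return(node)
  k <- .ad$k + 1L
  if (k > length(.ad$nodes)) .ad$nodes <- c(.ad$nodes, vector("list", length(.ad$nodes)))
  .ad$nodes[[k]] <- node
  .ad$k <- k
  node
}

.ad_new <- function(val, bw = NULL, leaf = FALSE) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$bw <- bw
  class(e) <- "ad_node"
  if (!leaf) .ad_record(e)
  e
}

#' Create a trainable parameter tensor
#'
#' Parameters live outside the tape; their gradients accumulate across a
#' backward pass and persist until [ad_zero_grad()].
#' @param x Numeric matrix of initial values.
#' @return An `ad_node` marked as a parameter.
#' @keywords internal
ad_param <- function(x) {
  e <- .ad_new(as.matrix(x), leaf = TRUE)
  class(e) <- c("ad_param", "ad_node")
  e
}

is_ad <- function(x) inherits(x, "ad_node")

#' Wrap a constant matrix as a node (no gradient tracking)
#' @keywords internal
ad_const <- function(x) .ad_new(as.matrix(x), leaf = TRUE)

.v <- function(x) if (is_ad(x)) x$val else as.matrix(x)

# Push gradient g into x if x tracks gradients.
.acc <- function(x, g) {
  if (!is_ad(x)) return(invisible(NULL))
  if (is.null(x$bw) && !inherits(x, "ad_param")) return(invisible(NULL))
  x$grad <- if (is.null(x$grad)) g else x$grad + g
  invisible(NULL)
}

#' Run backward pass from a scalar loss node
#' @param loss An `ad_node` holding a 1x1 value.
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(is_ad(loss), length(loss$val) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  if (.ad$k > 0L) {
    for (i in seq(.ad$k, 1L)) {
      n <- .ad$nodes[[i]]
      if (!is.null(n$grad) && !is.null(n$bw)) n$bw(n$grad)
    }
  }
  .ad$recording <- FALSE
  invisible(NULL)
}

#' Zero the gradients of a (nested) parameter collection
#' @param params Nested list of `ad_param` objects.
#' @keywords internal
ad_zero_grad <- function(params) {
  for (p in ad_collect_params(params)) p$grad <- NULL
  invisible(NULL)
}

#' Flatten a nested parameter structure into a list of ad_param
#' @keywords internal
ad_collect_params <- function(x) {
  if (inherits(x, "ad_param")) return(list(x))
  if (is.list(x)) return(do.call(c, c(lapply(x, ad_collect_params), list(list()))))
  list()
}

# ---- primitive ops ---------------------------------------------------------

#' Matrix product of two nodes
#' @keywords internal
ad_matmul <- function(a, b) {
  A <- .v(a); B <- .v(b)
  out <- .ad_new(A %*% B, bw = function(g) {
    .acc(a, g %*% t(B))
    .acc(b, t(A) %*% g)
  })
  out
}

# Addition with row-vector (1 x d) and scalar (1 x 1) broadcasting.
#' @keywords internal
ad_add <- function(a, b) {
  A <- .v(a); B <- .v(b)
  val <- if (nrow(B) == 1L && nrow(A) > 1L) {
    if (length(B) == 1L) A + B[1L] else sweep(A, 2L, B[1L, ], "+")
  } else if (length(B) == 1L && length(A) > 1L) A + B[1L] else A + B
  .ad_new(val, bw = function(g) {
    .acc(a, g)
    gb <- if (nrow(B) == 1L && nrow(A) > 1L) {
      if (length(B) == 1L) matrix(sum(g), 1L, 1L) else matrix(colSums(g), 1L)
    } else if (length(B) == 1L && length(A) > 1L) matrix(sum(g), 1L, 1L) else g
    .acc(b, gb)
  })
}

#' Elementwise product with row-vector/scalar broadcasting on `b`
#' @keywords internal
ad_mul <- function(a, b) {
  A <- .v(a); B <- .v(b)
  Bx <- if (nrow(B) == 1L && nrow(A) > 1L) {
    if (length(B) == 1L) matrix(B[1L], nrow(A), ncol(A)) else matrix(B[1L, ], nrow(A), ncol(A), byrow = TRUE)
  } else if (length(B) == 1L) matrix(B[1L], nrow(A), ncol(A)) else B
  .ad_new(A * Bx, bw = function(g) {
    .acc(a, g * Bx)
    gb <- g * A
    if (nrow(B) == 1L && nrow(A) > 1L) {
      gb <- if (length(B) == 1L) matrix(sum(gb), 1L, 1L) else matrix(colSums(gb), 1L)
    } else if (length(B) == 1L && length(A) > 1L) gb <- matrix(sum(gb), 1L, 1L)
    .acc(b, gb)
  })
}

#' Multiply a node by a fixed scalar
#' @keywords internal
ad_scale <- function(a, s) {
  A <- .v(a)
  .ad_new(A * s, bw = function(g) .acc(a, g * s))
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

#' @keywords internal
ad_tanh <- function(a) {
  y <- tanh(.v(a))
  .ad_new(y, bw = function(g) .acc(a, g * (1 - y * y)))
}

#' @keywords internal
ad_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-.v(a)))
  .ad_new(y, bw = function(g) .acc(a, g * y * (1 - y)))
}

#' @keywords internal
ad_relu <- function(a) {
  A <- .v(a)
  y <- pmax(A, 0)
  .ad_new(y, bw = function(g) .acc(a, g * (A > 0)))
}

#' @keywords internal
ad_leaky_relu <- function(a, alpha = 0.2) {
  A <- .v(a)
  y <- ifelse(A > 0, A, alpha * A)
  .ad_new(matrix(y, nrow(A)), bw = function(g) .acc(a, g * ifelse(A > 0, 1, alpha)))
}

#' @keywords internal
ad_exp <- function(a) {
  y <- exp(.v(a))
  .ad_new(y, bw = function(g) .acc(a, g * y))
}

#' @keywords internal
ad_log <- function(a) {
  A <- .v(a)
  .ad_new(log(A), bw = function(g) .acc(a, g / A))
}

#' Row-wise softmax (numerically stabilised)
#' @keywords internal
ad_softmax_rows <- function(a) {
  A <- .v(a)
  m <- apply(A, 1L, max)
  e <- exp(A - m)
  y <- e / rowSums(e)
  .ad_new(y, bw = function(g) {
    .acc(a, y * (g - rowSums(g * y)))
  })
}

#' Sum of all elements (1x1 result)
#' @keywords internal
ad_sum <- function(a) {
  A <- .v(a)
  .ad_new(matrix(sum(A), 1L, 1L), bw = function(g) .acc(a, matrix(g[1L], nrow(A), ncol(A))))
}

#' Mean of all elements (1x1 result)
#' @keywords internal
ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(.v(a)))

#' Column-wise max over a subset of rows; returns 1 x d
#'
#' Gradient flows to the (first) argmax row of each column.
#' @keywords internal
ad_colmax <- function(a, rows = NULL) {
  A <- .v(a)
  if (is.null(rows)) rows <- seq_len(nrow(A))
  sub <- A[rows, , drop = FALSE]
  wm <- apply(sub, 2L, which.max)
  y <- matrix(sub[cbind(wm, seq_len(ncol(sub)))], 1L)
  .ad_new(y, bw = function(g) {
    G <- matrix(0, nrow(A), ncol(A))
    G[cbind(rows[wm], seq_len(ncol(A)))] <- g[1L, ]
    .acc(a, G)
  })
}

#' Row selection (gather); duplicate indices allowed
#' @keywords internal
ad_rows <- function(a, idx) {
  A <- .v(a)
  idx <- as.integer(idx)
  .ad_new(A[idx, , drop = FALSE], bw = function(g) {
    G <- matrix(0, nrow(A), ncol(A))
    acc <- rowsum(g, group = idx)
    G[as.integer(rownames(acc)), ] <- acc
    .acc(a, G)
  })
}

#' Column selection
#' @keywords internal
ad_cols <- function(a, idx) {
  A <- .v(a)
  idx <- as.integer(idx)
  .ad_new(A[, idx, drop = FALSE], bw = function(g) {
    G <- matrix(0, nrow(A), ncol(A))
    acc <- rowsum(t(g), group = idx)
    G[, as.integer(rownames(acc))] <- t(acc)
    .acc(a, G)
  })
}

#' Transpose
#' @keywords internal
ad_t <- function(a) {
  A <- .v(a)
  .ad_new(t(A), bw = function(g) .acc(a, t(g)))
}

#' Stack nodes/matrices by row
#' @param xs List of nodes or constant matrices with equal column counts.
#' @keywords internal
ad_rbind <- function(xs) {
  vals <- lapply(xs, .v)
  nr <- vapply(vals, nrow, 1L)
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  .ad_new(do.call(rbind, vals), bw = function(g) {
    for (i in seq_along(xs)) .acc(xs[[i]], g[starts[i]:ends[i], , drop = FALSE])
  })
}

#' Stack nodes/matrices by column
#' @keywords internal
ad_cbind <- function(xs) {
  vals <- lapply(xs, .v)
  nc <- vapply(vals, ncol, 1L)
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  .ad_new(do.call(cbind, vals), bw = function(g) {
    for (i in seq_along(xs)) .acc(xs[[i]], g[, starts[i]:ends[i], drop = FALSE])
  })
}

#' Mean squared error between a prediction node and a constant target
#' @keywords internal
ad_mse_loss <- function(pred, target) {
  d <- ad_sub(pred, ad_const(target))
  ad_mean(ad_mul(d, d))
}

# ---- optimiser -------------------------------------------------------------

#' Adam optimiser step over a nested parameter collection
#'
#' First/second moment buffers are stored inside each parameter environment,
#' so repeated calls continue the same optimisation trajectory.
#' @param params Nested list of `ad_param`.
#' @param lr Learning rate.
#' @param t Step counter (1-based) for bias correction.
#' @param weight_decay Decoupled weight decay coefficient (AdamW-style);
#'   applied multiplicatively as `1 - lr * weight_decay` per step.
#' @keywords internal
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  for (p in ad_collect_params(params)) {
    if (is.null(p$grad)) next
    if (weight_decay > 0) p$val <- p$val * (1 - lr * weight_decay)
    if (is.null(p$adam_m)) {
      p$adam_m <- matrix(0, nrow(p$val), ncol(p$val))
      p$adam_v <- matrix(0, nrow(p$val), ncol(p$val))
    }
    p$adam_m <- beta1 * p$adam_m + (1 - beta1) * p$grad
    p$adam_v <- beta2 * p$adam_v + (1 - beta2) * p$grad^2
    mhat <- p$adam_m / (1 - beta1^t)
    vhat <- p$adam_v / (1 - beta2^t)
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

#' Extract plain numeric values from a nested parameter collection
#' @keywords internal
ad_param_values <- function(params) {
  if (inherits(params, "ad_param")) return(params$val)
  if (is.list(params)) return(lapply(params, ad_param_values))
  params
}

#' Load plain numeric values back into a nested parameter collection
#' @keywords internal
ad_param_load <- function(params, values) {
  if (inherits(params, "ad_param")) {
    params$val <- values
    return(invisible(NULL))
  }
  if (is.list(params)) for (i in seq_along(params)) ad_param_load(params[[i]], values[[i]])
  invisible(NULL)
}
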