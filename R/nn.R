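# Layer-level plumbing for the segmentation network.  The 3x3 convolutions,
# 2x2 max-pool and nearest upsampling run in compiled code (src/convnet.cpp);
# pointwise (1x1) convolutions, ReLU and the attention gates are plain matrix
# algebra here.

PAD_DEPTH_ZERO <- 0L
PAD_DEPTH_REFLECT <- 1L

#' Circular padding along the angular axis
#'
#' Pads rows by wrapping modulo the row count (the polar seam is physically
#' continuous: A-line `n-1` is adjacent to A-line 0), and columns (depth)
#' with zeros or symmetric reflection.  Every convolution in the network
#' pads this way, which is what makes predictions continuous across the
#' image seam.
#'
#' @param x matrix or 3-d array (rows x cols x channels).
#' @param pad_rows rows added on each side (must be < row count).
#' @param pad_cols columns added on each side.
#' @param depth_mode `"zero"` or `"reflect"` for the column padding.
#' @return padded array of the same rank.
#' @export
circular_pad <- function(x, pad_rows, pad_cols = 0L,
                         depth_mode = c("zero", "reflect")) {
  depth_mode <- match.arg(depth_mode)
  was_matrix <- is.matrix(x)
  if (was_matrix) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  if (pad_rows >= n) stop_config("pad_rows must be smaller than the row count")
  ri <- ((seq_len(n + 2L * pad_rows) - pad_rows - 1L) %% n) + 1L
  out <- x[ri, , , drop = FALSE]
  if (pad_cols > 0L) {
    left <- right <- array(0, c(dim(out)[1], pad_cols, C))
    if (depth_mode == "reflect") {
      left <- out[, pad_cols:1L, , drop = FALSE]
      right <- out[, W:(W - pad_cols + 1L), , drop = FALSE]
    }
    tmp <- array(0, c(dim(out)[1], W + 2L * pad_cols, C))
    tmp[, seq_len(pad_cols), ] <- left
    tmp[, pad_cols + seq_len(W), ] <- out
    tmp[, pad_cols + W + seq_len(pad_cols), ] <- right
    out <- tmp
  }
  if (was_matrix && dim(out)[3] == 1L) dim(out) <- dim(out)[1:2]
  out
}

# ---- compiled-layer wrappers -----------------------------------------------

conv3_fwd <- function(x, w4, b, pad_mode, relu = FALSE) {
  d <- dim(w4)
  .cpp_conv3x3_fwd(x, matrix(w4, 9L * d[3], d[4]), b, pad_mode, relu * 1L)
}

conv3_bwd <- function(x, w4, dy, pad_mode) {
  d <- dim(w4)
  r <- .cpp_conv3x3_bwd(x, matrix(w4, 9L * d[3], d[4]), dy, pad_mode)
  list(dx = r$dx, dw = array(r$dw, dim = d), db = r$db)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(dy, y) {
  dy[y <= 0] <- 0
  dy
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# 1x1 convolution as (H*W x Cin) %*% (Cin x Cout)
as_hwc <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

as_cube <- function(m, H, W) {
  dim(m) <- c(H, W, ncol(m))
  m
}

lin1x1_fwd <- function(x, w, b) {
  d <- dim(x)
  y <- as_hwc(x) %*% w
  y <- sweep(y, 2L, b, "+")
  as_cube(y, d[1], d[2])
}

lin1x1_bwd <- function(x, w, dy) {
  d <- dim(x)
  dym <- as_hwc(dy)
  xm <- as_hwc(x)
  list(dx = as_cube(tcrossprod(dym, w), d[1], d[2]),
       dw = crossprod(xm, dym),
       db = colSums(dym))
}

concat_c <- function(a, b) {
  d <- dim(a)
  array(c(a, b), c(d[1], d[2], d[3] + dim(b)[3]))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- instance normalization ------------------------------------------------
# Per-channel standardization over the spatial map with learned gain/bias,
# fused with ReLU.  Batch-size independent and invariant to circular row
# shifts, so it preserves the network's seam equivariance.

in_relu_fwd <- function(y, g, b, eps = 1e-5) {
  d <- dim(y)
  m <- as_hwc(y)
  mu <- colMeans(m)
  s <- sqrt(colMeans(m * m) - mu * mu + eps)
  xhat <- sweep(sweep(m, 2L, mu, "-"), 2L, s, "/")
  out <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  out[out < 0] <- 0
  list(a = as_cube(out, d[1], d[2]), xhat = xhat, s = s)
}

in_relu_bwd <- function(da, blk, g) {
  d <- dim(da)
  dm <- as_hwc(da)
  dm[as_hwc(blk$a) <= 0] <- 0
  xhat <- blk$xhat
  dg <- colSums(dm * xhat)
  db <- colSums(dm)
  dxhat <- sweep(dm, 2L, g, "*")
  n <- nrow(dm)
  mean1 <- colMeans(dxhat)
  mean2 <- colMeans(dxhat * xhat)
  dx <- sweep(dxhat - rep(mean1, each = n) - xhat * rep(mean2, each = n),
              2L, blk$s, "/")
  list(dx = as_cube(dx, d[1], d[2]), dg = dg, db = db)
}
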