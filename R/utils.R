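#' @importFrom rlang abort warn .data
#' @importFrom stats quantile rgamma runif rbinom median approx setNames
#' @importFrom utils head tail
#' @import tibble
NULL

# Gaussian kernel with half-width 3*sd, normalized to sum 1.
gauss_kernel <- function(sd) {
  if (sd <= 0) return(1)
  h <- max(1L, ceiling(3 * sd))
  k <- exp(-0.5 * ((-h:h) / sd)^2)
  k / sum(k)
}

# Smooth along columns (depth axis) with symmetric-reflection edges.
smooth_depth <- function(M, sd) {
  k <- gauss_kernel(sd)
  if (length(k) == 1L) return(M)
  h <- (length(k) - 1L) %/% 2L
  W <- ncol(M)
  out <- matrix(0, nrow(M), W)
  for (l in seq_along(k)) {
    off <- l - h - 1L
    j <- seq_len(W) + off
    j[j < 1L] <- 1L - (j[j < 1L])        # reflect: 0 -> 1, -1 -> 2
    j[j > W] <- 2L * W + 1L - j[j > W]
    out <- out + k[l] * M[, j, drop = FALSE]
  }
  out
}

# Smooth along rows (angular axis) with circular wraparound.
smooth_rows_circular <- function(M, sd) {
  k <- gauss_kernel(sd)
  if (length(k) == 1L) return(M)
  h <- (length(k) - 1L) %/% 2L
  n <- nrow(M)
  out <- matrix(0, n, ncol(M))
  for (l in seq_along(k)) {
    off <- l - h - 1L
    i <- ((seq_len(n) - 1L + off) %% n) + 1L
    out <- out + k[l] * M[i, , drop = FALSE]
  }
  out
}

# Trailing (causal) running mean along depth: value at column j averages
# columns max(1, j-w+1) .. j.  Used by the lumen detector so that a sharp
# lumen/tissue step is crossed exactly at the step, never before it.
trailing_mean_depth <- function(M, w) {
  if (w <= 1L) return(M)
  W <- ncol(M)
  cs <- t(apply(M, 1L, cumsum))
  lead <- cs
  lag <- cbind(matrix(0, nrow(M), min(w, W)),
               cs[, seq_len(max(0L, W - w)), drop = FALSE])
  denom <- pmin(seq_len(W), w)
  sweep(lead - lag, 2L, denom, "/")
}

# First TRUE per row, NA when a row has none.
first_true_by_row <- function(B) {
  any_true <- rowSums(B) > 0
  idx <- max.col(B, ties.method = "first")
  idx[!any_true] <- NA_integer_
  idx
}

# Circular running median (odd window), vectorized over shifted copies.
circular_running_median <- function(x, window) {
  stopifnot(window %% 2L == 1L)
  n <- length(x)
  h <- (window - 1L) %/% 2L
  shifted <- vapply(-h:h, function(off) x[((seq_len(n) - 1L + off) %% n) + 1L],
                    numeric(n))
  apply(shifted, 1L, median)
}

# Circular linear interpolation over NA runs.
interp_circular <- function(x) {
  n <- length(x)
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  if (all(ok)) return(x)
  idx <- which(ok)
  xx <- c(idx, idx + n, idx + 2L * n)
  yy <- rep(x[idx], 3L)
  approx(xx, yy, xout = which(!ok) + n)$y -> fill
  x[!ok] <- fill
  x
}

# Derive a child seed stream deterministically from a parent seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_data <- function(msg) abort(msg, class = "ivoctseg_data_error")
stop_config <- function(msg) abort(msg, class = "ivoctseg_config_error")
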