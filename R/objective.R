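#' Tversky index with exclusion masking
#'
#' Soft Tversky index over the valid (non-exclusion) pixels only:
#' `TI = (TP + s) / (TP + alpha*FP + beta*FN + s)` with soft counts
#' `TP = sum(p*t)`, `FP = sum(p*(1-t))`, `FN = sum((1-p)*t)`.  Pixels with
#' `valid = FALSE` contribute to no term, which is the whole point of the
#' exclusion category: unreadable depth can never move the loss.  With
#' `alpha = beta = 0.5` the index reduces to soft Dice
#' `2*sum(p*t) / (sum(p) + sum(t))`.
#'
#' @param probs per-pixel probabilities in `[0,1]` (any shape).
#' @param target binary map of the same shape.
#' @param valid logical map of the same shape (`NULL` = all valid).
#' @param alpha false-positive weight (>= 0).
#' @param beta false-negative weight (>= 0).
#' @param smooth stabilizer; an empty valid mask returns `TI = 1` by the
#'   `s/s` convention (flagged degenerate via attribute).
#' @return scalar in `[0,1]`.
#' @export
tversky_index <- function(probs, target, valid = NULL, alpha = 0.5,
                          beta = 0.5, smooth = 1e-6) {
  if (alpha < 0 || beta < 0) stop_config("alpha and beta must be >= 0")
  if (length(probs) != length(target)) stop_data("probs/target shape mismatch")
  if (!is.null(valid) && length(valid) != length(probs)) {
    stop_data("valid mask shape mismatch")
  }
  p <- as.vector(probs); t <- as.vector(target) * 1
  if (!is.null(valid)) {
    v <- as.vector(valid)
    p <- p[v]; t <- t[v]
  }
  degenerate <- length(p) == 0L
  tp <- sum(p * t)
  fp <- sum(p * (1 - t))
  fn <- sum((1 - p) * t)
  ti <- (tp + smooth) / (tp + alpha * fp + beta * fn + smooth)
  attr(ti, "degenerate") <- degenerate
  ti
}

#' Tversky focal loss
#'
#' `(1 - TI)^gamma`, the class-imbalance-aware objective used to train the
#' per-plaque-type networks, with parameters optimized by plaque type.
#' `alpha = beta = 0.5, gamma = 1` makes it `1 - soft Dice`.
#'
#' @inheritParams tversky_index
#' @param gamma focal exponent (> 0).
#' @return scalar in `[0,1]`.
#' @export
tversky_focal_loss <- function(probs, target, valid = NULL, alpha = 0.5,
                               beta = 0.5, gamma = 1, smooth = 1e-6) {
  if (gamma <= 0) stop_config("gamma must be > 0")
  ti <- tversky_index(probs, target, valid, alpha, beta, smooth)
  loss <- (1 - as.numeric(ti))^gamma
  attr(loss, "degenerate") <- attr(ti, "degenerate")
  loss
}

# Gradient of the focal Tversky loss w.r.t. probs, given pooled soft counts.
# Exclusion pixels receive exactly zero gradient.  Used with batch-pooled
# counts: pass tp/fp/fn accumulated over the whole batch.
tversky_focal_grad <- function(probs, target, valid, tp, fp, fn,
                               alpha, beta, gamma, smooth = 1e-6) {
  den <- tp + alpha * fp + beta * fn + smooth
  ti <- (tp + smooth) / den
  t <- target * 1
  # dTI/dp = (t*den - (tp+s)*(t + alpha*(1-t) - beta*t)) / den^2
  dti_dp <- (t * den - (tp + smooth) * (t + alpha * (1 - t) - beta * t)) / den^2
  dl_dti <- if (gamma == 1) -1 else -gamma * (1 - ti)^(gamma - 1)
  g <- dl_dti * dti_dp
  if (!is.null(valid)) g[!valid] <- 0
  g
}

#' Default per-plaque-type loss parameters
#'
#' Per-type `(alpha, beta, gamma)`: rarer, harder subtypes (the calcified
#' subtypes and fibrofatty) get a false-positive-leaning Tversky weighting
#' with a focal exponent; the commoner targets and the combined groups use
#' the soft-Dice setting.  All values are configurable per experiment; the
#' intent is to reproduce the procedure (parameters optimized by plaque
#' type), the published values being unavailable.
#'
#' @param target class or group name.
#' @return list with `alpha`, `beta`, `gamma`, `smooth`.
#' @export
default_loss_params <- function(target) {
  resolve_target(target)  # validates the name
  rare <- c("calcified_lipid", "calcified_fibrous", "fibrofatty")
  if (target %in% rare) {
    list(alpha = 0.7, beta = 0.3, gamma = 4 / 3, smooth = 1e-6)
  } else {
    list(alpha = 0.5, beta = 0.5, gamma = 1, smooth = 1e-6)
  }
}
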