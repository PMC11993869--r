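#' Sørensen-Dice coefficient
#'
#' Twice the cardinality of the set intersection over the sum of the
#' individual set cardinalities, computed over valid (non-exclusion)
#' pixels.  When both sets are empty the frame is degenerate (a correct
#' all-negative prediction) and the coefficient is 1 with a `degenerate`
#' attribute set; such frames are excluded from frame-mean Dice.
#'
#' @param pred,truth binary maps of identical shape.
#' @param valid logical map; `NULL` means all pixels count.
#' @return numeric in `[0,1]` with attribute `degenerate`.
#' @export
dice_coefficient <- function(pred, truth, valid = NULL) {
  if (length(pred) != length(truth)) stop_data("pred/truth shape mismatch")
  p <- as.vector(pred) > 0
  t <- as.vector(truth) > 0
  if (!is.null(valid)) {
    v <- as.vector(valid)
    p <- p[v]; t <- t[v]
  }
  np <- sum(p); nt <- sum(t)
  if (np + nt == 0L) {
    return(structure(1, degenerate = TRUE))
  }
  structure(2 * sum(p & t) / (np + nt), degenerate = FALSE)
}

#' A-line positivity labels
#'
#' An A-line (row) is positive iff at least `min_pixels` of its valid
#' pixels are positive.  This is the reduction behind A-line-level
#' sensitivity and specificity.
#'
#' @param mask binary matrix (rows = A-lines).
#' @param valid logical matrix; `NULL` = all valid.
#' @param min_pixels positivity threshold in pixels.
#' @return logical vector, one entry per A-line.
#' @export
aline_positive <- function(mask, valid = NULL, min_pixels = 1L) {
  stopifnot(is.matrix(mask))
  m <- (mask > 0) * 1
  if (!is.null(valid)) m <- m * (valid * 1)
  rowSums(m) >= min_pixels
}

#' A-line confusion counts and rates
#'
#' Reduces predicted and true masks to per-A-line labels with
#' [aline_positive()], then counts the confusion over A-lines.  A-lines
#' with no valid pixel are dropped from every count.  Rates are `NA` (not
#' zero) when their denominator is empty.
#'
#' @inheritParams aline_positive
#' @param pred,truth binary matrices of identical shape.
#' @return one-row tibble: `tp, fp, fn, tn, sensitivity, specificity,
#'   n_alines`.
#' @export
aline_confusion <- function(pred, truth, valid = NULL, min_pixels = 1L) {
  if (!all(dim(pred) == dim(truth))) stop_data("pred/truth shape mismatch")
  keep <- if (is.null(valid)) rep(TRUE, nrow(pred)) else rowSums(valid) > 0
  pv <- aline_positive(pred, valid, min_pixels)[keep]
  tv <- aline_positive(truth, valid, min_pixels)[keep]
  tp <- sum(pv & tv); fp <- sum(pv & !tv)
  fn <- sum(!pv & tv); tn <- sum(!pv & !tv)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    n_alines = sum(keep)
  )
}

#' Evaluate a model (or predictions) over a set of frames
#'
#' Computes per-frame Dice in the flattened crop domain, reporting the
#' frame-mean over non-degenerate frames as the headline number with
#' pixel-pooled Dice logged alongside, and pools A-line confusion counts
#' over all frames before deriving sensitivity and specificity.
#'
#' @param samples list of evaluation samples, each a list with `x`
#'   (flattened intensity matrix) and `mask` (three-category training
#'   mask); build them with [prepare_training_samples()].
#' @param model an `ivoct_model`; alternatively supply `predictions`, a
#'   list of binary matrices aligned with `samples`.
#' @param threshold probability cut for binarization.
#' @param min_pixels A-line positivity rule.
#' @param predictions optional precomputed binary masks (bypasses the
#'   model).
#' @return an `ivoct_eval` list: `metrics` (one-row tibble), `per_frame`
#'   tibble.
#' @export
evaluate_dataset <- function(samples, model = NULL, threshold = 0.5,
                             min_pixels = 1L, predictions = NULL) {
  if (is.null(model) && is.null(predictions)) {
    stop_config("supply a model or precomputed predictions")
  }
  if (length(samples) == 0) stop_data("no frames to evaluate")
  missing_truth <- which(vapply(samples, function(s) is.null(s$mask), logical(1)))
  if (length(missing_truth) > 0) {
    stop_data(paste0("missing ground truth for frame(s) ",
                     paste(head(missing_truth, 10), collapse = ", ")))
  }
  rows <- vector("list", length(samples))
  pooled_i <- 0; pooled_u <- 0
  for (f in seq_along(samples)) {
    s <- samples[[f]]
    valid <- s$mask != MASK_EXCLUSION
    truth <- s$mask == MASK_TARGET
    pred <- if (!is.null(predictions)) predictions[[f]] > 0 else {
      predict_frame(model, s$x, threshold)$mask
    }
    d <- dice_coefficient(pred, truth, valid)
    pv <- pred & valid; tv <- truth & valid
    pooled_i <- pooled_i + sum(pv & tv)
    pooled_u <- pooled_u + sum(pv) + sum(tv)
    cf <- aline_confusion(pred, truth, valid, min_pixels)
    rows[[f]] <- tibble::tibble(
      frame = f, dice = as.numeric(d),
      degenerate = attr(d, "degenerate"),
      tp = cf$tp, fp = cf$fp, fn = cf$fn, tn = cf$tn,
      n_alines = cf$n_alines
    )
  }
  per_frame <- dplyr::bind_rows(rows)
  ok <- !per_frame$degenerate
  tp <- sum(per_frame$tp); fp <- sum(per_frame$fp)
  fn <- sum(per_frame$fn); tn <- sum(per_frame$tn)
  metrics <- tibble::tibble(
    dice_mean = if (any(ok)) mean(per_frame$dice[ok]) else NA_real_,
    dice_pooled = if (pooled_u > 0) 2 * pooled_i / pooled_u else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, fp = fp, fn = fn, tn = tn,
    n_frames = length(samples),
    n_degenerate = sum(per_frame$degenerate)
  )
  structure(list(metrics = metrics, per_frame = per_frame),
            class = "ivoct_eval")
}

#' @export
print.ivoct_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<ivoct_eval> %d frames | Dice (frame mean) %.3f | pooled %.3f | A-line sens %.3f spec %.3f\n",
    m$n_frames, m$dice_mean, m$dice_pooled, m$sensitivity, m$specificity))
  invisible(x)
}
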